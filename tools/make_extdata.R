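#!/usr/bin/env Rscript
# Regenerates the packaged plain-text fixtures under inst/extdata/.
# Both files are synthetic (graded-response-model humans; uniform
# bots) and byte-identical across runs for the default seed.
library(scump)
paths <- make_fixtures(dir = file.path("inst", "extdata"))
cat("wrote:", paths, sep = "\n  ")
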