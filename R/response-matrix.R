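#' Likert-type response matrix
#'
#' Container for an `n x d` grid of integer Likert-type responses with
#' inclusive category bounds (default 1..5), a missing-value mask, item
#' names and respondent identifiers. All downstream machinery (index
#' computation, classification, simulation) consumes this class.
#'
#' @param values integer matrix (or coercible), respondents in rows,
#'   items in columns. `NA` entries are recorded in the missing mask.
#' @param categories length-2 integer vector `c(low, high)` of inclusive
#'   category bounds; default `c(1, 5)`.
#' @param item_ids optional character vector of item names (default from
#'   column names or `item1..itemd`); must be unique.
#' @param row_ids optional respondent identifiers (default row numbers).
#' @return an object of class `response_matrix` with fields `values`
#'   (integer matrix, `NA` where missing), `categories`, `missing_mask`,
#'   `item_ids`, `row_ids`.
#' @examples
#' rm <- response_matrix(matrix(c(1L, 3L, 5L, 2L, NA, 4L), nrow = 3))
#' n_missing(rm)
#' @export
response_matrix <- function(values, categories = c(1L, 5L),
                            item_ids = NULL, row_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2L)
    stop("a response matrix needs at least 2 items (columns)")
  if (nrow(values) < 1L)
    stop("a response matrix needs at least 1 respondent (row)")
  categories <- as.integer(categories)
  if (length(categories) != 2L || categories[1] >= categories[2])
    stop("categories must be c(low, high) with low < high")
  storage <- suppressWarnings(apply(values, 2, as.numeric))
  storage <- matrix(as.numeric(storage), nrow = nrow(values))
  if (any(!is.na(storage) & storage != round(storage)))
    stop("non-integer response values found")
  mask <- is.na(storage)
  inr <- !mask & (storage < categories[1] | storage > categories[2])
  if (any(inr))
    stop(sprintf("%d response value(s) outside category bounds [%d, %d]",
                 sum(inr), categories[1], categories[2]))
  item_ids <- item_ids %||% colnames(values) %||%
    paste0("item", seq_len(ncol(values)))
  if (anyDuplicated(item_ids))
    stop("item_ids must be unique")
  row_ids <- row_ids %||% rownames(values) %||%
    as.character(seq_len(nrow(values)))
  vals <- matrix(as.integer(storage), nrow = nrow(storage),
                 dimnames = list(row_ids, item_ids))
  structure(list(values = vals, categories = categories,
                 missing_mask = mask, item_ids = as.character(item_ids),
                 row_ids = as.character(row_ids)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items, categories %d..%d, %d missing cell(s)\n",
              nrow(x$values), ncol(x$values), x$categories[1],
              x$categories[2], sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Number of masked cells in a response matrix
#' @param rm a [response_matrix].
#' @return integer count of missing cells.
#' @export
n_missing <- function(rm) sum(rm$missing_mask)

#' Read a Likert-type response matrix from delimited text
#'
#' Expects one header row of item names and one row per respondent.
#' Cells matching `missing_codes` become masked; any other non-integer
#' or out-of-range cell is an error.
#'
#' @param path file path to a CSV/TSV file.
#' @param sep field delimiter; `","` (default) or `"\t"`.
#' @param categories inclusive category bounds, default `c(1, 5)`.
#' @param missing_codes character tokens to treat as missing;
#'   default `c("", "NA", "NaN")`.
#' @param id_col optional name of a leading respondent-id column; it is
#'   removed from the items and used as `row_ids`.
#' @param label_col optional name of a class-label column (0 = human,
#'   1 = bot). When given, a [labeled_sample] is returned instead.
#' @param drop_all_missing drop rows whose items are all missing, with a
#'   logged warning (default `TRUE`).
#' @return a [response_matrix], or a [labeled_sample] if `label_col` is
#'   given.
#' @export
read_response_matrix <- function(path, sep = ",", categories = c(1L, 5L),
                                 missing_codes = c("", "NA", "NaN"),
                                 id_col = NULL, label_col = NULL,
                                 drop_all_missing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (nrow(df) == 0L) stop("empty response file: ", path)
  row_ids <- NULL
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("id column not found: ", id_col)
    row_ids <- df[[id_col]]
    df[[id_col]] <- NULL
  }
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df)) stop("label column not found: ", label_col)
    labels <- as.integer(df[[label_col]])
    df[[label_col]] <- NULL
  }
  mat <- as.matrix(df)
  mat[mat %in% missing_codes] <- NA
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- !is.na(mat) & is.na(num)
  if (any(bad))
    stop(sprintf("%d unparseable cell(s), e.g. '%s'", sum(bad), mat[bad][1]))
  rm <- response_matrix(num, categories = categories,
                        item_ids = names(df), row_ids = row_ids)
  if (drop_all_missing) {
    all_miss <- rowSums(rm$missing_mask) == ncol(rm$values)
    if (any(all_miss)) {
      scump_log(sum(all_miss), " row(s) with all items missing dropped")
      keep <- !all_miss
      rm <- response_matrix(rm$values[keep, , drop = FALSE],
                            categories = rm$categories,
                            item_ids = rm$item_ids,
                            row_ids = rm$row_ids[keep])
      if (!is.null(labels)) labels <- labels[keep]
    }
  }
  if (is.null(labels)) rm else labeled_sample(rm, labels)
}

#' Write a response matrix to delimited text
#'
#' Inverse of [read_response_matrix()]: one header row of item ids, one
#' row per respondent, masked cells written as `NA`. Integer matrices
#' round-trip bit-identically.
#'
#' @param rm a [response_matrix].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(rm, path, sep = ",") {
  out <- rm$values
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Impute masked cells with the middle category
#'
#' Standard preprocessing before index computation: every missing cell
#' becomes the middle category of the scale (e.g. 3 on a 1..5 scale).
#' Requires an odd number of categories so the middle is unambiguous.
#'
#' @param rm a [response_matrix].
#' @return a [response_matrix] with an empty missing mask; idempotent.
#' @export
impute_middle <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  K <- rm$categories[2] - rm$categories[1] + 1L
  if (K %% 2L == 0L)
    stop(sprintf("middle-category imputation is ambiguous for an even number of categories (K = %d)", K))
  if (!any(rm$missing_mask)) return(rm)
  mid <- as.integer((rm$categories[1] + rm$categories[2]) / 2L)
  vals <- rm$values
  vals[rm$missing_mask] <- mid
  response_matrix(vals, categories = rm$categories,
                  item_ids = rm$item_ids, row_ids = rm$row_ids)
}

#' Labeled calibration sample
#'
#' A [response_matrix] plus one binary class label per row (0 = human,
#' 1 = bot). Each class must have at least 2 rows so per-class feature
#' parameters are estimable.
#'
#' @param responses a [response_matrix].
#' @param labels integer vector of 0/1 labels, one per row.
#' @return an object of class `labeled_sample` with fields `responses`,
#'   `labels`, `n0` (humans), `n1` (bots).
#' @export
labeled_sample <- function(responses, labels) {
  stopifnot(inherits(responses, "response_matrix"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(responses$values))
    stop("labels length must equal the number of respondent rows")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (human) or 1 (bot)")
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 < 2L) stop("calibration sample needs at least 2 human rows")
  if (n1 < 2L) stop("calibration sample needs at least 2 bot rows")
  structure(list(responses = responses, labels = labels, n0 = n0, n1 = n1),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("<labeled_sample> %d humans + %d bots, %d items\n",
              x$n0, x$n1, ncol(x$responses$values)))
  invisible(x)
}

## subset rows of a response_matrix, keeping metadata
rm_subset <- function(rm, idx) {
  response_matrix(rm$values[idx, , drop = FALSE], categories = rm$categories,
                  item_ids = rm$item_ids, row_ids = rm$row_ids[idx])
}

## rbind two response matrices with identical items/categories
rm_bind <- function(a, b) {
  stopifnot(identical(a$item_ids, b$item_ids),
            identical(a$categories, b$categories))
  response_matrix(rbind(a$values, b$values), categories = a$categories,
                  item_ids = a$item_ids,
                  row_ids = make.unique(c(a$row_ids, b$row_ids)))
}
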