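item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12,item13,item14,item15,item16,item17,item18,item19,item20,item21,item22,item23,item24,item25,item26,item27,item28,item29,item30,item31,item32
5,3,3,5,4,4,5,4,1,5,3,2,4,5,4,1,4,1,5,3,1,2,4,4,5,1,3,1,4,4,3,3
5,3,5,2,4,1,3,1,1,5,2,1,4,2,1,1,4,1,5,3,2,5,4,3,5,4,4,3,4,5,3,5
1,4,5,2,3,1,2,3,1,2,1,2,1,3,3,1,4,2,2,1,1,2,4,3,3,3,4,3,4,2,4,3
5,2,2,2,4,2,2,2,1,5,3,5,2,5,2,1,4,3,5,1,1,5,4,4,5,2,5,1,4,3,3,3
1,2,5,1,3,4,4,4,1,2,3,1,2,5,1,1,4,5,5,3,2,5,4,4,5,4,5,2,5,4,3,4
5,2,2,2,3,1,2,4,5,5,5,1,5,5,5,1,4,3,5,3,2,2,4,4,4,1,4,1,3,3,3,1
1,2,2,2,3,1,2,2,1,4,3,1,2,3,1,2,4,3,5,3,2,1,3,2,1,1,4,1,1,3,2,1
5,3,3,3,5,1,4,4,2,2,5,1,2,5,1,2,4,3,5,3,2,5,5,5,5,3,5,5,4,5,4,4
5,3,5,3,3,2,5,4,1,5,5,2,5,5,2,3,4,4,5,1,2,5,4,4,5,2,4,3,4,4,3,3
1,2,2,1,3,1,2,1,2,1,1,1,5,3,1,2,4,3,3,3,1,1,4,4,5,4,5,5,5,5,4,5
5,1,3,3,3,4,4,1,1,5,1,3,2,5,1,1,4,4,5,1,2,3,5,1,5,2,4,3,4,4,3,3
1,1,2,1,3,1,2,1,1,5,2,1,2,3,4,1,2,1,1,1,1,1,3,1,5,1,4,1,4,4,2,1
3,2,3,4,5,4,4,2,2,5,3,2,4,5,5,1,4,2,1,1,2,1,5,1,1,2,4,3,3,4,2,3
5,3,5,2,4,2,2,4,5,5,5,1,5,5,1,1,4,5,4,3,2,5,4,4,1,2,2,5,5,2,2,4
1,2,4,2,3,1,5,1,5,5,3,2,5,5,5,2,3,1,2,1,1,1,4,3,4,3,5,1,3,3,3,1
4,2,2,1,2,1,2,3,1,2,1,4,2,3,1,1,2,1,3,3,1,1,4,1,4,1,5,3,3,4,3,4
1,1,2,2,3,1,2,1,1,3,3,1,2,5,1,1,4,2,4,3,2,4,4,3,5,3,5,5,5,5,4,2
5,3,4,2,4,1,2,4,2,1,3,1,2,1,1,1,4,4,5,1,1,2,4,4,4,1,4,1,3,1,3,2
1,2,2,2,2,1,2,2,1,2,3,1,2,5,1,1,4,1,5,4,1,1,5,2,1,2,5,1,5,4,3,4
1,2,2,2,3,1,2,1,1,5,3,1,2,4,1,1,2,1,3,3,2,5,4,2,2,1,5,1,3,2,3,3
1,2,5,2,4,1,2,1,2,5,3,1,3,5,5,1,4,4,5,3,2,5,5,4,5,3,4,1,3,5,3,4
1,1,3,1,3,4,2,2,1,5,1,1,3,3,1,1,4,2,5,3,2,5,4,4,5,3,5,3,4,4,3,5
5,5,5,5,5,4,5,5,2,2,4,2,5,5,5,2,4,1,5,1,2,2,4,4,5,4,5,2,4,4,3,4
5,3,5,2,5,3,5,4,5,5,3,4,5,4,5,1,4,1,3,3,2,2,4,4,1,3,5,4,4,3,3,3
5,2,5,2,4,4,5,4,2,5,3,4,5,5,5,1,4,3,5,3,2,5,5,4,5,4,5,5,4,4,4,3
5,3,2,5,5,4,4,5,5,5,5,2,5,5,5,3,5,5,5,3,5,5,4,4,5,4,5,5,5,5,4,5
5,1,2,2,3,2,2,4,1,4,2,4,2,4,1,1,4,2,5,3,1,3,5,4,5,2,5,3,4,4,3,5
5,2,2,2,5,4,2,4,5,5,3,1,2,1,5,1,4,4,5,3,2,5,4,4,5,2,2,3,5,5,3,4
1,5,5,2,4,4,3,4,2,5,3,4,4,5,4,2,2,1,3,3,1,1,1,1,5,1,5,3,4,5,3,3
2,4,3,4,2,1,1,1,1,3,4,1,2,5,4,1,2,1,1,5,2,4,5,4,5,3,5,2,4,4,3,4
5,2,4,2,3,4,2,4,5,5,5,4,5,5,5,2,4,2,5,1,1,1,2,4,4,1,5,1,3,4,3,3
1,1,2,5,2,1,2,1,1,2,3,1,2,3,1,3,4,1,5,1,2,1,4,5,1,1,1,1,3,1,3,3
5,3,2,5,3,4,2,4,5,5,3,4,5,5,5,3,5,4,5,4,2,5,5,4,4,2,3,1,1,4,3,2
4,2,5,2,4,1,2,2,1,1,1,1,3,3,1,1,4,3,5,3,1,2,4,3,5,2,3,1,3,4,2,1
1,2,3,2,3,1,2,1,1,1,2,1,2,5,1,3,4,3,3,3,2,2,4,4,5,3,5,2,4,5,3,2
5,2,5,2,3,1,2,1,2,5,3,2,5,5,1,1,4,5,5,1,2,5,5,5,5,1,4,2,3,2,3,3
5,3,4,2,5,4,2,4,5,5,4,4,5,5,5,3,5,5,3,4,3,5,5,4,5,3,5,5,4,5,3,4
2,1,3,2,2,1,3,1,1,4,3,1,2,4,1,1,4,4,1,1,4,2,2,4,2,1,4,3,1,4,2,4
1,1,3,2,3,1,2,2,2,5,5,1,3,5,5,3,4,4,3,3,2,5,5,4,5,1,5,3,4,4,3,3
4,2,5,4,4,4,3,2,1,2,3,2,4,5,1,1,4,1,3,1,2,5,3,2,5,2,5,3,5,5,3,4
3,1,3,5,4,1,3,2,5,5,2,4,4,5,1,1,4,1,5,1,2,2,5,4,5,4,5,5,5,5,4,5
1,1,5,2,2,1,4,1,5,5,3,4,3,5,2,1,4,2,5,1,2,5,4,4,5,3,4,3,4,4,3,4
5,2,2,4,5,1,2,2,1,2,1,1,2,5,1,1,4,5,5,3,4,5,5,5,5,3,4,1,3,4,3,4
5,5,3,5,5,4,5,5,5,5,2,2,4,5,4,1,4,4,5,3,2,5,4,5,5,3,5,4,3,5,3,5
5,3,5,3,5,4,2,4,5,5,5,4,5,5,5,1,4,3,5,3,5,4,4,4,5,3,5,3,4,4,3,3
5,3,5,5,4,4,3,4,1,1,3,1,1,3,1,1,2,1,3,3,1,1,3,3,3,1,2,1,3,2,2,3
5,2,2,3,5,4,3,4,2,5,3,2,5,5,1,2,4,5,5,3,2,5,4,3,5,2,4,2,5,4,2,3
1,1,5,1,2,1,2,1,1,2,2,1,4,4,1,1,4,5,5,4,2,4,5,3,2,1,4,1,1,5,2,3
3,2,5,5,1,1,2,4,1,5,2,1,2,5,1,1,4,1,5,1,2,4,4,5,5,1,4,1,4,2,3,3
1,1,5,2,4,1,2,2,3,5,1,1,2,5,1,1,3,1,5,1,2,2,4,1,5,1,3,3,3,2,3,3
5,2,2,3,5,3,3,1,1,2,2,4,4,5,1,1,4,4,5,1,1,2,5,4,5,3,5,1,4,2,3,4
3,2,2,2,2,1,2,2,1,5,2,1,3,5,1,1,4,1,5,1,1,1,3,4,4,1,3,1,3,3,1,2
1,2,2,2,5,1,2,4,1,1,2,1,2,3,1,1,4,3,5,3,2,5,4,1,1,1,3,1,3,1,3,1
4,2,5,3,4,1,5,4,5,5,3,4,5,5,5,1,4,1,5,1,2,5,5,4,5,1,3,2,3,4,3,3
5,5,4,5,3,4,5,4,5,5,5,4,5,5,5,3,5,5,5,4,5,5,5,5,5,5,5,3,5,5,4,5
5,2,5,1,3,1,2,2,2,4,3,1,5,5,5,1,4,4,5,3,2,5,4,3,5,1,5,4,3,5,3,1
5,3,3,5,3,1,2,5,1,2,2,2,2,3,1,1,1,1,5,1,2,1,3,4,2,2,5,1,1,4,3,3
4,3,2,3,3,4,2,2,5,5,5,4,5,5,5,3,5,5,5,4,2,5,5,5,5,1,5,3,4,5,3,4
5,2,5,5,3,1,2,5,2,4,4,4,4,5,5,2,4,5,3,3,2,5,4,5,4,3,5,2,4,5,3,3
5,3,5,2,5,4,4,4,2,2,3,2,3,5,1,1,2,4,5,1,2,1,5,4,1,1,3,1,3,2,3,1
5,3,2,2,3,4,5,4,4,5,4,4,5,5,4,1,4,4,5,3,1,5,4,4,5,3,4,5,5,4,3,4
1,2,4,2,4,1,2,2,1,1,2,1,4,2,1,1,4,1,5,1,1,1,4,2,4,3,4,2,3,4,3,3
5,3,2,2,5,4,4,4,1,5,3,1,5,5,2,1,5,4,5,3,4,5,4,4,5,3,5,4,5,5,4,5
4,2,3,1,5,1,2,2,1,4,1,1,2,4,1,1,4,1,5,1,1,5,4,3,5,3,4,2,5,3,3,3
5,3,5,2,5,4,3,5,1,5,3,1,5,5,1,1,2,4,4,1,1,1,4,4,5,3,5,2,4,5,3,4
1,1,2,4,3,1,2,2,5,5,5,4,5,5,2,2,4,2,5,1,2,1,5,4,5,3,5,3,3,2,3,4
4,3,3,2,4,1,2,1,2,2,3,1,2,4,1,1,4,1,5,1,1,5,4,4,5,3,5,2,4,4,3,4
1,1,2,5,2,1,2,4,5,5,5,2,5,5,5,3,4,4,5,3,1,4,5,4,5,3,5,5,4,4,3,4
1,3,2,2,4,4,2,4,5,5,5,1,5,5,5,1,4,2,5,3,2,3,4,5,4,2,5,3,4,4,3,4
5,4,5,5,4,4,5,2,1,5,4,4,2,5,4,1,4,5,5,3,5,2,5,4,2,1,5,2,4,3,3,4
1,2,3,2,2,4,5,4,1,5,3,1,2,3,1,1,4,2,3,3,1,5,4,2,5,3,5,2,4,5,3,4
1,1,1,1,1,1,2,1,2,4,3,2,4,5,2,1,4,2,5,1,1,2,4,4,5,2,4,1,3,3,2,2
5,2,5,3,4,4,2,4,2,5,3,1,5,5,4,1,4,5,5,3,2,5,5,4,5,4,5,1,4,4,3,5
4,2,5,3,3,1,4,2,1,2,2,1,2,2,1,1,2,1,1,1,1,2,4,4,5,2,4,1,4,4,3,2
4,2,5,3,4,1,2,2,5,5,3,2,5,5,4,1,4,3,5,3,2,5,5,4,5,3,5,2,4,5,3,3
5,4,5,5,4,4,5,5,5,5,3,4,5,5,4,2,5,4,5,3,2,4,5,4,1,1,5,2,3,3,2,3
4,3,2,2,2,4,2,2,1,5,5,4,5,5,5,2,2,4,5,1,1,3,4,4,1,3,4,5,4,2,3,5
1,2,2,2,3,1,2,2,5,5,3,4,5,5,5,1,4,2,5,1,1,1,2,3,5,3,5,3,5,4,4,4
5,3,2,3,4,1,2,2,5,5,5,4,5,5,5,2,4,5,5,3,3,5,5,5,5,3,5,4,3,4,3,4
1,2,5,5,5,2,2,4,5,5,5,4,5,4,5,1,4,1,3,3,2,1,5,4,5,1,5,1,4,3,3,3
1,1,4,5,4,1,2,1,2,5,4,4,5,5,5,3,4,1,4,3,2,3,4,3,5,2,4,2,3,3,3,4
4,5,5,5,5,4,5,5,5,2,3,4,5,5,4,3,4,2,5,4,2,5,5,5,5,2,4,2,4,3,3,3
4,2,3,3,4,4,4,2,5,5,3,4,5,5,3,2,4,1,5,1,2,1,4,4,1,1,4,1,3,2,3,1
5,4,5,2,4,4,4,4,5,4,5,4,5,5,4,1,4,5,5,1,5,5,4,5,5,4,5,3,5,5,4,5
4,2,3,5,3,1,4,1,1,5,3,1,5,5,4,1,4,2,3,1,2,5,4,3,2,1,5,4,4,4,3,4
1,2,3,3,3,1,2,2,2,5,4,1,5,5,5,3,2,1,3,3,1,2,5,2,2,3,3,3,3,4,3,1
1,3,3,4,4,3,2,2,5,5,5,2,5,5,5,1,4,3,5,1,1,1,4,4,5,3,4,2,3,5,3,3
5,2,5,4,5,4,2,4,1,5,2,1,3,5,1,1,4,2,5,3,2,5,4,3,5,3,5,1,4,4,3,4
1,1,5,1,4,1,2,1,1,5,3,1,3,5,1,1,4,4,5,1,2,2,4,4,4,1,5,1,3,1,2,4
5,1,4,2,4,1,4,2,3,5,3,1,5,5,2,3,4,1,5,1,2,2,5,2,4,3,4,1,3,3,2,3
1,1,5,1,4,1,2,4,1,2,3,1,2,3,1,1,2,1,2,1,1,1,2,4,5,2,5,3,3,3,3,3
5,2,5,3,5,4,4,3,2,5,5,4,5,5,5,1,5,5,5,4,2,5,5,5,5,3,5,3,4,5,3,3
5,1,2,2,5,1,4,2,2,2,2,2,5,3,5,1,5,4,2,1,2,2,5,3,1,3,4,2,4,5,3,3
4,1,2,2,4,1,2,1,5,5,3,5,5,5,5,1,4,4,5,1,2,5,3,4,5,4,5,2,5,4,2,4
1,1,5,5,3,2,4,2,1,4,3,5,2,1,1,1,4,1,5,3,2,5,4,4,5,3,5,4,4,4,3,1
4,2,3,2,5,4,1,2,1,4,3,4,5,5,1,2,4,3,5,3,2,2,5,5,4,2,5,5,4,5,3,3
1,1,5,2,5,1,3,5,1,1,1,1,2,5,1,1,5,3,5,3,2,5,5,4,4,2,4,2,5,4,2,3
1,2,1,4,3,4,2,4,2,5,3,4,5,5,4,2,5,5,5,3,2,5,5,4,5,4,5,3,5,5,4,4
1,1,2,2,4,4,2,2,5,5,4,4,5,5,5,1,4,1,4,1,1,1,4,4,5,3,5,5,5,5,4,5
1,2,2,2,3,1,2,1,1,2,2,1,2,2,1,1,4,1,5,1,2,1,4,1,4,2,5,2,3,3,3,1
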