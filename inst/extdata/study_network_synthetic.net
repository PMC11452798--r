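*Vertices 31
1 "1"
2 "2"
3 "3"
4 "4"
5 "5"
6 "6"
7 "7"
8 "8"
9 "9"
10 "10"
11 "11"
12 "12"
13 "13"
14 "14"
15 "15"
16 "16"
17 "17"
18 "18"
19 "19"
20 "20"
21 "21"
22 "22"
23 "23"
24 "24"
25 "25"
26 "26"
27 "27"
28 "28"
29 "29"
30 "30"
31 "31"
*Edges
1 6
1 8
1 24
1 28
2 3
2 21
3 17
4 23
4 24
5 8
5 20
5 27
6 7
7 31
8 21
9 13
9 17
9 24
10 12
10 14
10 18
10 25
11 26
11 27
11 28
11 29
12 14
12 29
13 18
13 28
13 30
13 31
14 15
15 28
16 21
16 27
17 29
18 23
19 22
19 31
20 26
21 30
22 29
23 30
24 25
24 30
25 30
10 30
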