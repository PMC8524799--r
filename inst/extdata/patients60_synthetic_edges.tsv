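4	5
6	8
2	11
1	15
11	16
13	17
14	19
18	22
14	24
18	24
5	25
9	25
23	25
1	28
3	30
3	31
6	31
20	31
25	31
28	31
23	32
26	32
4	33
17	33
4	34
8	34
25	34
30	34
23	35
25	36
8	37
17	37
33	37
23	38
14	39
18	39
27	39
31	39
37	39
32	40
36	40
10	41
12	41
22	41
30	41
6	42
27	42
33	42
36	42
41	42
3	43
4	43
15	43
30	43
31	43
33	43
37	43
38	43
3	44
4	44
7	44
11	44
12	44
21	44
40	44
14	45
30	45
31	45
16	46
31	46
16	47
37	47
43	47
3	48
16	48
32	48
29	49
4	50
13	50
14	50
24	50
37	50
42	50
44	50
9	51
10	51
18	51
25	51
44	51
6	52
16	52
20	52
25	52
36	52
3	53
38	53
7	54
15	54
30	54
35	54
48	54
53	54
22	55
27	55
50	55
51	55
26	56
2	57
3	57
24	57
1	58
6	58
7	58
23	58
31	58
39	58
41	58
44	58
56	58
30	59
44	59
47	59
54	59
21	60
24	60
29	60
45	60
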