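id,Age,Gender,Marriage,Smoke,Zip,Diagnosis
1,56,F,Divorce,Y,33613,AA
2,60,F,Marriage,N,33647,Diabetes
3,81,M,Single,N,34660,AA
4,44,M,Divorce,Y,32801,AA
5,56,M,Marriage,N,32211,AA
6,34,M,Marriage,N,32868,Normal
7,73,F,Single,N,34768,AA
8,77,M,Marriage,N,33102,AA
9,84,F,Single,N,32855,AA
10,68,F,Marriage,N,33709,ACML
11,66,F,Marriage,Y,34302,Diabetes
12,53,M,Single,Y,34565,AML
13,59,M,Marriage,Y,32652,AITCL
14,63,F,Marriage,N,33615,Normal
15,19,F,Single,N,75865,AML
16,38,M,Single,Y,33650,Normal
17,56,M,Marriage,N,75677,Normal
18,67,F,Marriage,N,33218,AA
19,65,M,Marriage,N,34813,ACML
20,71,M,Marriage,N,32556,Normal
21,67,F,Marriage,Y,33451,AML FROM MDS
22,60,M,Marriage,Y,33648,Normal
23,56,F,Divorce,N,33613,AA
24,60,F,Marriage,Y,33647,AA
25,51,M,Single,N,34660,ACML
26,34,M,Divorce,N,32801,Normal
27,56,M,Marriage,N,32211,AML FROM MDS
28,34,M,Marriage,Y,32868,ACML
29,38,M,Marriage,N,72868,ACML
30,73,F,Single,N,34768,AA
31,57,F,Marriage,N,33102,AA
32,84,F,Single,N,32855,AA
33,60,F,Marriage,N,33709,Diabetes
34,66,F,Marriage,Y,34302,ACML
35,73,M,Single,N,34565,AML
36,59,M,Marriage,N,32652,AITCL
37,43,F,Marriage,Y,33615,AML
38,29,F,Single,Y,75865,AML
39,48,M,Single,N,33650,AML
40,76,M,Marriage,N,75677,Normal
41,37,F,Marriage,Y,33218,AML
42,45,M,Marriage,N,34813,AML
43,51,M,Marriage,N,32556,AITCL
44,67,F,Marriage,N,33451,AML
45,60,M,Marriage,N,33648,Normal
46,56,F,Divorce,Y,33613,AA
47,63,F,Marriage,N,33647,AA
48,56,M,Marriage,N,34660,Normal
49,34,M,Divorce,Y,32801,AML
50,52,M,Marriage,N,32211,AITCL
51,34,M,Marriage,N,32868,Normal
52,43,F,Single,Y,34768,AA
53,38,M,Marriage,Y,75685,AML FROM MDS
54,42,M,Marriage,Y,72512,ACML
55,26,M,Single,Y,75828,ACML
56,33,F,Single,N,34574,AA
57,47,M,Marriage,Y,34543,ACML
58,62,F,Marriage,Y,32767,Normal
59,55,M,Marriage,Y,75926,AML
60,42,M,Marriage,Y,75384,AML
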