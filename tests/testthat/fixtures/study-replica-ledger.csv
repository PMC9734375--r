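seq,date,sample,activity,wells_used,plate_size,note,user,machine
1,2020-01-13,20200113mChOCT4sg2,Transfect,96,96,distributed into 96-well plates with carrier cells,,
2,2020-01-14,20200113mChOCT4sg2,Feed w Ri,,,,,
3,2020-01-15,20200113mChOCT4sg2,Feed w mTeSr+,,,,,
4,2020-01-16,20200113mChOCT4sg2,Image,,,screen wells for single fluorescent clusters,,
5,2020-01-16,20200113mChOCT4sg2_C6,Image,,,single fluorescent cluster observed,,
6,2020-01-16,20200113mChOCT4sg2_A2,Image,,,single fluorescent cluster observed,,
7,2020-01-16,20200113mChOCT4sg2_B3,Image,,,single fluorescent cluster observed,,
8,2020-01-16,20200113mChOCT4sg2_D4,Image,,,single fluorescent cluster observed,,
9,2020-01-16,20200113mChOCT4sg2_E5,Image,,,single fluorescent cluster observed,,
10,2020-01-18,20200113mChOCT4sg2_A2,Passage,,,,,
11,2020-01-21,20200113mChOCT4sg2_A2,Passage,,,,,
12,2020-01-23,20200113mChOCT4sg2_A2,Discontinue,,,population lost fluorescence,,
13,2020-01-18,20200113mChOCT4sg2_B3,Passage,,,,,
14,2020-01-21,20200113mChOCT4sg2_B3,Passage,,,,,
15,2020-01-23,20200113mChOCT4sg2_B3,Discontinue,,,population lost fluorescence,,
16,2020-01-18,20200113mChOCT4sg2_D4,Passage,,,,,
17,2020-01-21,20200113mChOCT4sg2_D4,Passage,,,,,
18,2020-01-23,20200113mChOCT4sg2_D4,Discontinue,,,population lost fluorescence,,
19,2020-01-18,20200113mChOCT4sg2_E5,Passage,,,,,
20,2020-01-21,20200113mChOCT4sg2_E5,Passage,,,,,
21,2020-01-23,20200113mChOCT4sg2_E5,Discontinue,,,population lost fluorescence,,
22,2020-01-18,20200113mChOCT4sg2_C6,Passage,,,,,
23,2020-01-20,20200113mChOCT4sg2_C6,Sort,,,,,
24,2020-01-21,20200113mChOCT4sg2_C6_Sort1,Feed w Ri,,,,,
25,2020-01-23,20200113mChOCT4sg2_C6_Sort1,Passage,,,,,
26,2020-01-25,20200113mChOCT4sg2_C6_Sort1,Sort,,,,,
27,2020-01-27,20200113mChOCT4sg2_C6_Sort2,Passage,,,,,
28,2020-01-29,20200113mChOCT4sg2_C6_Sort2,Freeze,4,24,bank of purified population,,
29,2020-02-02,20200113mChOCT4sg2_C6_Sort2,Thaw,,,,,
30,2020-02-04,20200113mChOCT4sg2_C6_Sort2,Passage,,,,,
31,2020-02-06,20200113mChOCT4sg2_C6_Sort2,Extract DNA,,,,,
32,2020-02-07,20200113mChOCT4sg2_C6_Sort2,Send out for analysis,,,"genomic analysis: copy number, insertion-site PCR, STR, mycoplasma",,
33,2020-01-20,20200120mCHOCT4sg2,Transfect,96,96,distributed into 96-well plates with carrier cells,,
34,2020-01-21,20200120mCHOCT4sg2,Feed w Ri,,,,,
35,2020-01-22,20200120mCHOCT4sg2,Feed w mTeSr+,,,,,
36,2020-01-23,20200120mCHOCT4sg2,Image,,,screen wells for single fluorescent clusters,,
37,2020-01-23,20200120mCHOCT4sg2_B9,Image,,,single fluorescent cluster observed,,
38,2020-01-23,20200120mCHOCT4sg2_A1,Image,,,single fluorescent cluster observed,,
39,2020-01-23,20200120mCHOCT4sg2_C2,Image,,,single fluorescent cluster observed,,
40,2020-01-23,20200120mCHOCT4sg2_D3,Image,,,single fluorescent cluster observed,,
41,2020-01-23,20200120mCHOCT4sg2_F6,Image,,,single fluorescent cluster observed,,
42,2020-01-25,20200120mCHOCT4sg2_A1,Passage,,,,,
43,2020-01-28,20200120mCHOCT4sg2_A1,Passage,,,,,
44,2020-01-30,20200120mCHOCT4sg2_A1,Discontinue,,,population lost fluorescence,,
45,2020-01-25,20200120mCHOCT4sg2_C2,Passage,,,,,
46,2020-01-28,20200120mCHOCT4sg2_C2,Passage,,,,,
47,2020-01-30,20200120mCHOCT4sg2_C2,Discontinue,,,population lost fluorescence,,
48,2020-01-25,20200120mCHOCT4sg2_D3,Passage,,,,,
49,2020-01-28,20200120mCHOCT4sg2_D3,Passage,,,,,
50,2020-01-30,20200120mCHOCT4sg2_D3,Discontinue,,,population lost fluorescence,,
51,2020-01-25,20200120mCHOCT4sg2_F6,Passage,,,,,
52,2020-01-28,20200120mCHOCT4sg2_F6,Passage,,,,,
53,2020-01-30,20200120mCHOCT4sg2_F6,Discontinue,,,population lost fluorescence,,
54,2020-01-25,20200120mCHOCT4sg2_B9,Passage,,,,,
55,2020-01-27,20200120mCHOCT4sg2_B9,Sort,,,,,
56,2020-01-28,20200120mCHOCT4sg2_B9_Sort1,Feed w Ri,,,,,
57,2020-01-30,20200120mCHOCT4sg2_B9_Sort1,Passage,,,,,
58,2020-02-01,20200120mCHOCT4sg2_B9_Sort1,Sort,,,,,
59,2020-02-03,20200120mCHOCT4sg2_B9_Sort2,Passage,,,,,
60,2020-02-05,20200120mCHOCT4sg2_B9_Sort2,Freeze,4,24,bank of purified population,,
61,2020-02-09,20200120mCHOCT4sg2_B9_Sort2,Thaw,,,,,
62,2020-02-11,20200120mCHOCT4sg2_B9_Sort2,Passage,,,,,
63,2020-02-13,20200120mCHOCT4sg2_B9_Sort2,Extract DNA,,,,,
64,2020-02-14,20200120mCHOCT4sg2_B9_Sort2,Send out for analysis,,,"genomic analysis: copy number, insertion-site PCR, STR, mycoplasma",,
65,2020-02-20,20200220mChOCT4sg2,Transfect,96,96,distributed into 96-well plates with carrier cells,,
66,2020-02-21,20200220mChOCT4sg2,Feed w Ri,,,,,
67,2020-02-22,20200220mChOCT4sg2,Feed w mTeSr+,,,,,
68,2020-02-23,20200220mChOCT4sg2,Image,,,screen wells for single fluorescent clusters,,
69,2020-02-23,20200220mChOCT4sg2_A7,Image,,,single fluorescent cluster observed,,
70,2020-02-23,20200220mChOCT4sg2_C6,Image,,,single fluorescent cluster observed,,
71,2020-02-23,20200220mChOCT4sg2_C10,Image,,,single fluorescent cluster observed,,
72,2020-02-23,20200220mChOCT4sg2_B2,Image,,,single fluorescent cluster observed,,
73,2020-02-23,20200220mChOCT4sg2_G8,Image,,,single fluorescent cluster observed,,
74,2020-02-25,20200220mChOCT4sg2_B2,Passage,,,,,
75,2020-02-28,20200220mChOCT4sg2_B2,Passage,,,,,
76,2020-03-01,20200220mChOCT4sg2_B2,Discontinue,,,population lost fluorescence,,
77,2020-02-25,20200220mChOCT4sg2_G8,Passage,,,,,
78,2020-02-28,20200220mChOCT4sg2_G8,Passage,,,,,
79,2020-03-01,20200220mChOCT4sg2_G8,Discontinue,,,population lost fluorescence,,
80,2020-02-25,20200220mChOCT4sg2_A7,Passage,,,,,
81,2020-02-27,20200220mChOCT4sg2_A7,Sort,,,,,
82,2020-02-28,20200220mChOCT4sg2_A7_Sort1,Feed w Ri,,,,,
83,2020-03-01,20200220mChOCT4sg2_A7_Sort1,Passage,,,,,
84,2020-03-03,20200220mChOCT4sg2_A7_Sort1,Sort,,,,,
85,2020-03-05,20200220mChOCT4sg2_A7_Sort2,Passage,,,,,
86,2020-03-07,20200220mChOCT4sg2_A7_Sort2,Freeze,4,24,bank of purified population,,
87,2020-03-11,20200220mChOCT4sg2_A7_Sort2,Thaw,,,,,
88,2020-03-13,20200220mChOCT4sg2_A7_Sort2,Passage,,,,,
89,2020-03-15,20200220mChOCT4sg2_A7_Sort2,Extract DNA,,,,,
90,2020-03-16,20200220mChOCT4sg2_A7_Sort2,Send out for analysis,,,"genomic analysis: copy number, insertion-site PCR, STR, mycoplasma",,
91,2020-02-25,20200220mChOCT4sg2_C6,Passage,,,,,
92,2020-02-27,20200220mChOCT4sg2_C6,Sort,,,,,
93,2020-02-28,20200220mChOCT4sg2_C6_Sort1,Feed w Ri,,,,,
94,2020-03-01,20200220mChOCT4sg2_C6_Sort1,Passage,,,,,
95,2020-03-03,20200220mChOCT4sg2_C6_Sort1,Sort,,,,,
96,2020-03-05,20200220mChOCT4sg2_C6_Sort2,Passage,,,,,
97,2020-03-07,20200220mChOCT4sg2_C6_Sort2,Freeze,4,24,bank of purified population,,
98,2020-03-11,20200220mChOCT4sg2_C6_Sort2,Thaw,,,,,
99,2020-03-13,20200220mChOCT4sg2_C6_Sort2,Passage,,,,,
100,2020-03-15,20200220mChOCT4sg2_C6_Sort2,Extract DNA,,,,,
101,2020-03-16,20200220mChOCT4sg2_C6_Sort2,Send out for analysis,,,"genomic analysis: copy number, insertion-site PCR, STR, mycoplasma",,
102,2020-02-25,20200220mChOCT4sg2_C10,Passage,,,,,
103,2020-02-27,20200220mChOCT4sg2_C10,Sort,,,,,
104,2020-02-28,20200220mChOCT4sg2_C10_Sort1,Feed w Ri,,,,,
105,2020-03-01,20200220mChOCT4sg2_C10_Sort1,Passage,,,,,
106,2020-03-03,20200220mChOCT4sg2_C10_Sort1,Sort,,,,,
107,2020-03-05,20200220mChOCT4sg2_C10_Sort2,Passage,,,,,
108,2020-03-07,20200220mChOCT4sg2_C10_Sort2,Sort,,,population still heterogeneous,,
109,2020-03-09,20200220mChOCT4sg2_C10_Sort3,Passage,,,,,
110,2020-03-11,20200220mChOCT4sg2_C10_Sort3,Sort,,,,,
111,2020-03-13,20200220mChOCT4sg2_C10_Sort4,Passage,,,,,
112,2020-03-15,20200220mChOCT4sg2_C10_Sort4,Passage,,,,,
113,2020-03-17,20200220mChOCT4sg2_C10_Sort4,Freeze,4,24,bank of purified population,,
114,2020-03-21,20200220mChOCT4sg2_C10_Sort4,Thaw,,,,,
115,2020-03-23,20200220mChOCT4sg2_C10_Sort4,Passage,,,,,
116,2020-03-25,20200220mChOCT4sg2_C10_Sort4,Extract DNA,,,,,
117,2020-03-26,20200220mChOCT4sg2_C10_Sort4,Send out for analysis,,,"genomic analysis: copy number, insertion-site PCR, STR, mycoplasma",,
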