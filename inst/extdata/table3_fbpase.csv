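compound_no,observed,garf_pred,rf_pred,is_test,source
1,7,6.62,6.7,0,b29
2,6.4,6.2,6.25,1,b29
3,5.92,5.99,6.05,0,b29
4,6.66,6.63,6.61,0,b29
5,6.3,6.05,6.27,1,b29
6,6.74,6.61,6.64,0,b29
7,7.1,6.85,6.89,0,b29
8,6.05,6.23,6.16,0,b29
9,5.7,5.65,5.73,0,b29
10,7.6,7.38,7.2,1,b29
11,6,5.95,6.08,0,b29
12,5,5.69,5.66,0,b29
13,5.56,5.75,6.03,0,b29
14,6.3,6.38,6.39,1,b29
15,4.87,5.33,5.4,0,b29
16,5.1,5.93,5.78,1,b29
17,5.3,5.4,5.55,0,b29
18,6.35,6.38,6.42,0,b29
19,6.92,6.84,6.8,0,b29
20,6.3,6.73,6.55,0,b29
21,7.52,7.29,7.13,1,b29
22,7.55,7.04,7.01,1,b29
23,7.24,6.99,7.14,0,b29
24,7.92,7.58,7.51,0,b29
25,7.72,7.61,7.54,0,b29
26,7.68,7.67,7.58,1,b29
27,8,7.8,7.83,0,b29
28,7.7,7.62,7.53,0,b29
29,7.74,7.36,7.44,0,b29
30,7.23,7.18,7.08,0,b29
31,6.82,6.85,6.82,0,b29
32,6.25,6.16,6.45,1,b29
33,7.15,7.03,6.97,0,b29
34,7.3,6.99,6.88,1,b29
35,7,6.87,6.36,1,b29
36,7.8,7.09,7.29,0,b29
37,7.48,7.32,7.24,0,b29
38,7.8,7.21,7.03,1,b29
39,7.62,7.5,7.46,0,b29
40,7.62,7.52,7.53,0,b29
41,6.52,6.7,6.58,1,b29
42,5.77,5.94,6.22,0,b29
43,7.85,7.55,7.48,0,b29
44,7.82,7.25,7.43,0,b29
45,6.07,6.56,6.45,0,b29
46,7.85,7.68,7.64,1,b29
47,7.37,7.51,7.52,1,b29
48,7.68,7.6,7.62,0,b29
49,7.66,7.61,7.64,0,b29
50,7.68,7.41,7.4,1,b29
51,7.06,7.21,7.1,0,b29
52,7.85,7.48,7.36,1,b29
53,7.8,7.71,7.68,0,b29
54,7.89,7.76,7.75,0,b29
55,7.49,7.45,7.48,0,b29
56,7.39,7.3,7,0,b29
57,7.47,7.31,7.23,1,b29
58,7.92,7.66,7.61,0,b29
59,7.4,7.12,7.22,0,b29
60,7.36,7.17,7.2,1,b29
61,5,5.41,5.78,0,b29
62,7.3,6.9,6.92,0,b29
63,6.02,6.42,6.69,1,b29
64,5.7,5.74,5.94,0,b29
65,5.89,6.06,6.01,0,b29
66,6.87,6.71,6.39,1,b29
67,6.68,7.05,6.89,1,b29
68,7.1,7.42,7.27,1,b29
69,6.92,6.38,6.13,1,b30
70,5,5.6,5.43,0,b30
71,6.85,6.7,6.51,0,b30
72,6.77,6.64,6.54,0,b30
73,6.68,6.54,6.35,1,b30
74,6.49,6.24,6.29,0,b30
75,6.8,6.78,6.8,0,b30
76,6.05,6.23,6.12,0,b30
77,6.59,6.47,6.59,0,b30
78,7.15,6.97,6.91,0,b30
79,6.96,7.01,7.02,0,b30
80,6.92,6.64,7.05,1,b30
81,5.4,5.79,6.08,0,b30
82,7.17,7.06,6.7,0,b30
83,7.42,7.1,6.85,1,b30
84,7.4,7.13,7.14,0,b30
85,7.07,6.95,6.91,0,b30
86,7.52,7.23,7.2,0,b30
87,6.07,6.1,6.22,0,b30
88,6.22,6.24,6.14,0,b30
89,5,5.48,5.43,0,b30
90,5.72,5.87,5.8,1,b30
91,5.68,5.61,5.54,0,b30
92,5.66,5.79,5.78,1,b30
93,5.37,5.55,5.62,0,b30
94,6.02,6.09,5.94,0,b30
95,5,5.43,5.68,1,b30
96,5.17,5.49,5.54,0,b30
97,5.15,5.5,5.43,0,b30
98,6.38,6.19,5.72,1,b30
99,6.42,6.39,6.17,0,b30
100,6.55,6.46,6.08,1,b30
101,6.24,6.36,6.19,1,b30
102,6.6,6.32,5.98,1,b30
103,6.46,6.3,6.1,1,b30
104,5,5.45,5.54,0,b30
105,5,5.35,5.45,0,b30
106,5.3,5.55,5.47,0,b31
107,5.26,5.58,5.56,0,b31
108,7.38,6.95,6.87,0,b31
109,4,4.36,4.62,1,b32
110,3.85,4.27,4.56,1,b32
111,4,4.27,4.44,0,b32
112,4.04,4.2,4.26,0,b32
113,4,4.14,4.2,1,b32
114,4.46,4.35,4.42,0,b32
115,4,4.19,4.5,1,b32
116,4,4.04,4.16,0,b32
117,4,4.19,4.28,1,b32
118,3.84,4.03,4.29,0,b32
119,4.64,4.09,4.38,1,b32
120,5.3,4.95,4.95,0,b32
121,4.32,4.55,4.71,0,b32
122,4.4,4.13,4.21,1,b32
123,3.82,4.43,4.5,0,b32
124,3.6,4.11,4.17,0,b32
125,4.3,4.46,4.41,0,b32
126,4.3,4.61,4.59,0,b32
127,4.15,4.31,4.47,0,b32
128,5.85,5.54,5.54,0,b32
129,5.48,5.22,5.19,0,b32
130,5.82,5.7,5.78,0,b32
131,5.7,5.69,5.76,0,b32
132,5.74,5.65,5.76,0,b32
133,5.82,5.81,5.82,0,b32
134,6.1,5.87,5.87,0,b32
135,6.15,5.52,5.42,1,b32
136,4.55,4.95,4.99,0,b32
137,5.35,5.52,5.4,1,b32
138,6.05,5.83,5.91,0,b32
139,5.8,5.66,5.67,1,b32
140,5.3,5.72,5.74,1,b32
141,5.26,5.27,5.27,0,b32
142,5.96,5.54,5.42,1,b32
143,4.89,5.56,5.42,1,b32
144,5.22,5.49,5.7,1,b33
145,5.65,5.8,5.88,0,b33
146,5.96,6,6.03,0,b33
147,5.82,5.91,6,1,b33
148,6.1,6.03,6.02,0,b33
149,6.1,6.04,6.01,0,b33
150,5.82,5.87,5.81,0,b33
151,5.6,5.64,5.63,0,b33
152,5.49,5.57,5.64,0,b33
153,6,5.94,5.85,0,b33
154,5.3,5.72,5.7,1,b33
155,5.02,5.26,5.34,0,b33
156,5.15,5.5,5.51,0,b33
157,5.6,5.63,5.59,0,b33
158,5.38,5.74,5.68,1,b33
159,5.73,5.87,5.75,1,b33
160,5.4,6.02,6.08,1,b33
161,5.6,5.86,5.87,1,b33
162,5.52,5.69,5.66,0,b33
163,6.15,6.41,6.25,1,b33
164,6.3,6.23,6.24,0,b33
165,6.7,6.52,6.56,0,b33
166,6.05,6.19,6.11,0,b33
167,6.4,6.32,6.29,0,b33
168,6.4,6.21,6.14,1,b33
169,7,6.56,6.47,1,b33
170,6.82,6.83,6.57,1,b33
171,6.07,6.42,6.38,0,b33
172,7.26,6.54,6.53,1,b33
173,6,6.09,6.03,0,b33
174,6.35,6.34,6.3,0,b33
175,7,6.77,6.67,1,b33
176,6.89,6.75,6.67,0,b33
177,6.65,6.66,6.59,0,b33
178,5,5.53,5.6,0,b33
179,6.55,6.9,6.94,1,b33
180,7.22,7.08,7.1,0,b33
181,7.05,6.79,6.83,1,b33
182,6.74,6.74,6.75,0,b33
183,7.05,6.94,6.81,0,b33
184,7.26,7.07,7.06,0,b33
185,7,6.99,7.02,0,b33
186,6.68,6.7,6.67,0,b33
187,7,6.92,6.99,0,b33
188,7.1,6.97,7.05,0,b33
189,7.26,6.72,6.73,0,b33
190,7.15,6.74,6.78,1,b33
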