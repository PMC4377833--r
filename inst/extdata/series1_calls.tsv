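case	BAT25_ngs	BAT25_pcr	BAT26_ngs	BAT26_pcr	D5S346_ngs	D5S346_pcr	BAT34c4_ngs	D18S55_ngs	status_ngs	status_pcr
1	-	-	-	-	-	-	-	-	Stable	Stable
2	-	-	-	-	-	-	-	-	Stable	Stable
3	+	+	+	+	+	+	+	-	High	High
4	+	+	+	+	+	+	+	+	High	High
5	-	-	-	-	-	-	-	-	Stable	Stable
6	+	+	+	+	-	-	-	+	High	High
7	-	-	-	-	-	-	-	-	Stable	Stable
8	+	+	+	+	+	+	+	+	High	High
9	+	+	+	+	-	-	-	-	High	High
10	+	+	+	+	-	-	+	+	High	High
11	-	-	-	-	-	-	-	-	Stable	Stable
12	-	-	-	-	-	-	-	-	Stable	Stable
13	-	-	-	-	-	-	-	-	Stable	Stable
14	-	-	-	-	-	-	-	-	Stable	Stable
15	+	+	+	+	-	-	+	+	High	High
16	-	-	-	-	-	-	-	-	Stable	Stable
17	-	-	-	-	-	-	-	-	Stable	Stable
18	+	+	+	+	-	+	+	-	High	High
19	+	+	+	+	+	+	+	+	High	High
20	-	-	-	-	-	-	-	-	Stable	Stable
21	-	-	-	-	-	-	-	+	Low	Stable
22	-	-	-	-	-	-	-	-	Stable	Stable
23	-	-	-	-	-	-	-	-	Stable	Stable
24	-	-	-	-	-	-	-	-	Stable	Stable
25	-	-	-	-	-	-	-	-	Stable	Stable
26	+	+	+	+	+	+	-	+	High	High
27	+	+	+	+	-	-	+	+	High	High
28	-	-	-	-	-	-	-	-	Stable	Stable
29	+	+	+	+	-	-	+	-	High	High
30	-	-	-	-	-	-	-	-	Stable	Stable
31	-	-	-	-	-	-	-	-	Stable	Stable
32	+	+	+	+	-	+	-	-	High	High
33	-	-	-	-	-	-	-	-	Stable	Stable
34	+	+	+	+	-	+	+	-	High	High
35	-	-	-	-	-	-	-	-	Stable	Stable
36	-	-	-	-	-	-	-	-	Stable	Stable
37	+	+	+	+	+	-	+	+	High	High
38	-	-	-	-	-	-	-	-	Stable	Stable
39	-	-	-	-	-	-	-	-	Stable	Stable
40	-	-	-	-	-	-	-	-	Stable	Stable
41	-	-	-	-	-	-	-	-	Stable	Stable
42	+	+	+	+	+	+	+	-	High	High
43	+	+	+	+	+	-	+	+	High	High
44	-	-	-	-	-	-	-	-	Stable	Stable
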