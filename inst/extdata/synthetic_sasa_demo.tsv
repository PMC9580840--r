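residue	L	sasa
A	3	154.459
A	5	137.106
A	7	131.929
A	9	127.743
A	11	124.223
A	13	120.585
A	15	116.447
A	17	115.894
A	19	115.136
A	21	111.813
A	23	110.073
A	25	109.187
A	27	106.026
A	29	106.001
A	31	105.66
A	33	106.636
A	35	101.699
A	37	102.876
A	39	98.58
A	41	98.604
A	43	98.837
A	45	98.811
C	3	136.982
C	5	122.585
C	7	112.607
C	9	106.123
C	11	101.151
C	13	96.396
C	15	92.065
C	17	89.961
C	19	88.789
C	21	84.812
C	23	84.532
C	25	81.429
C	27	81.957
C	29	77.886
C	31	78.719
C	33	76.24
C	35	74.047
C	37	72.137
C	39	72.612
C	41	71.795
C	43	70.323
C	45	70.035
K	3	165.345
K	5	163.433
K	7	155.909
K	9	151.186
K	11	150.992
K	13	153.662
K	15	148.414
K	17	149.279
K	19	149.228
K	21	148.374
K	23	145.969
K	25	143.322
K	27	141.155
K	29	141.999
K	31	142.508
K	33	141.962
K	35	141.357
K	37	138.615
K	39	138.173
K	41	137.958
K	43	137.3
K	45	137.356
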