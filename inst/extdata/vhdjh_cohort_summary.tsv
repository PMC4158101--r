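pair	sample_id	phase	unique_rearrangements	unique_per_1e3
1	1D	diagnosis	311	0.69
1	1R1	relapse	265	0.50
1	1R2	relapse	NA	NA
1	1R3	relapse	396	0.66
2	2D	diagnosis	315	0.72
2	2R1	relapse	3131	7.27
2	2R2	relapse	NA	NA
3	3D1	diagnosis	950	1.84
3	3R2	relapse	745	1.29
4	4D	diagnosis	9158	23.08
4	4PR	progression	1785	4.34
5	9D	diagnosis	2911	4.27
5	9R	relapse	18683	25.72
6	12D	diagnosis	7570	22.12
6	12R	relapse	7299	13.78
7	13D1	diagnosis	7931	27.09
7	13D2	diagnosis	2436	6.65
7	13R	relapse	1204	3.71
8	14D	diagnosis	4172	12.07
8	14R	relapse	1206	3.84
9	15D1	diagnosis	8727	15.47
9	15D2	diagnosis	955	2.83
9	15R	relapse	1296	4.62
10	16D	diagnosis	11303	12.10
10	16R	relapse	1875	2.67
11	F6D	diagnosis	786	1.04
11	F6PR	progression	2135	4.03
12	F7D	diagnosis	3491	6.07
12	F7R	relapse	6115	14.58
13	SPF6-1	diagnosis	1160	2.41
13	SPF6-2	diagnosis	828	1.75
13	SPF6-3	relapse	719	1.54
14	SPF10-1	diagnosis	1463	3.17
14	SPF10-2	relapse	1731	3.73
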