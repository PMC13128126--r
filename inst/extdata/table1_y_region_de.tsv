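gene	y_specificity	baseMean1	padj1	log2FC1	baseMean2	padj2	log2FC2
DtKita1h1_04777.t1.p1	Y_specific	317.5	1.20E-63	5.44	143.8	9.10E-31	5.69
DtKita1h1_04754.t1.p1	Y_specific	501.3	1.90E-21	-2.18	484.7	0.0017	-2.06
DtKita1h1_04791.t1.p1	Y_specific	627.2	5.88E-11	1.11	624.3	0.42	0.21
DtKita1h1_04764.t1	Y_specific	62.9	6.60E-11	7.53	145.7	0.70	-0.68
DtKita1h1_04801.t1.p1	Y_specific	39.6	8.20E-11	8.73	24.8	0.0014	2.70
DtKita1h1_04799.t1.p1	Y_specific	62.2	4.40E-10	7.51	75.7	0.68	0.59
DtKita1h1_04768.t1	Y_specific	27.5	2.30E-09	8.20	40.9	0.88	0.17
DtKita1h1_04787.t1.p1	Y_specific	21.7	2.40E-07	4.36	25.4	0.61	0.59
DtKita1h1_04782.t1.p1	Y_specific	12.5	1.80E-06	7.06	9.0	0.11	2.08
DtKita1h1_04746.t1.p1	Y_specific	12.1	5.10E-06	7.02	69.1	0.14	-2.17
DtKita1h1_04794.t1.p1	Y_specific	141.1	1.60E-05	-1.09	98.4	0.31	-0.56
DtKita1h1_04797.t1.p1	Y_specific	6.7	2.80E-05	6.16	6.1	0.26	1.37
DtKita1h1_04792.t1.p1	Y_specific	8.7	3.90E-05	6.54	8.7	0.36	1.09
DtKita1h1_04755.t1.p1	Y_specific	52.5	0.047	-0.85	22.9	0.56	0.60
DtKita1h1_04793.t1.p3	Y_specific	44.1	0.078	-0.80	19.9	0.50	0.56
DtKita1h1_04786.t1.p1	Y_specific	487.7	0.083	-0.32	482.5	0.30	-0.60
DtKita1h1_04769.t1.p4	Y_specific	6.3	0.12	-2.16	1.7	0.96	0.20
DtKita1h1_04770.t1.p1	Y_specific	8.3	0.13	-1.87	1.5	0.81	1.57
DtKita1h1_04758.t1.p1	Y_specific	94.6	0.22	0.47	43.6	0.04	1.73
DtKita1h1_04776.t1.p1	Y_specific	72.7	0.28	-0.38	31.0	0.064	1.12
DtKita1h1_04767.t1.p1	Y_specific	3.6	0.51	1.05	6.2	0.69	-0.83
DtKita1h1_04785.t1	Y_specific	195.1	0.73	-0.10	215.9	0.14	-0.65
DtKita1h1_04779.t1.p1	Y_specific	7.8	0.99	0.01	7.1	0.85	-0.22
DtKita1h1_04795.t1	Y_specific	1.5	NA	2.90	1.5	0.72	0.92
DtKita1h1_04762.t1	Y_specific	0.7	NA	1.40	0.2	0.77	1.95
DtKita1h1_04788.t1.p1	Y_specific	0.2	NA	0.92	0.1	0.95	0.52
DtKita1h1_04773.t1	Y_specific	0.2	NA	0.92	0.2	0.98	0.15
DtKita1h1_04751.t1	Y_specific	0.5	NA	0.88	0.3	0.92	0.73
DtKita1h1_04790.t1	Y_specific	1.7	NA	0.60	3	0.75	-1.06
DtKita1h1_04752.t1	Y_specific	0	NA	NA	0	NA	NA
DtKita1h1_04753.t1	Y_specific	0	NA	NA	0	NA	NA
DtKita1h1_04756.t1	Y_specific	0	NA	NA	0	NA	NA
DtKita1h1_04765.t1	Y_specific	0	NA	NA	0.2	0.87	-1.17
DtKita1h1_04771.t1	Y_specific	0	NA	NA	0.1	0.91	-0.81
DtKita1h1_04772.t1	Y_specific	0	NA	NA	0	NA	NA
DtKita1h1_04759.t1.p1	XY_gametolog	1705.0	2.05E-25	-1.26	1391.8	0.16	-0.98
DtKita1h1_04749.t1.p1	XY_gametolog	28.2	1.35E-09	8.24	24.1	0.18	1.49
DtKita1h1_04766.t1.p1	XY_gametolog	847.8	1.84E-05	-0.50	538.2	0.90	0.11
DtKita1h1_04748.t1.p1	XY_gametolog	35.2	0.00040	1.97	64.7	0.75	-0.66
DtKita1h1_04796.t1.p1	XY_gametolog	876.0	0.0012	0.34	737.1	0.68	0.14
DtKita1h1_04778.t1.p1	XY_gametolog	675.4	0.0029	-0.59	489.4	0.60	-0.22
DtKita1h1_04774.t1.p1	XY_gametolog	339.2	0.012	-0.40	245.1	0.86	-0.07
DtKita1h1_04775.t1.p1	XY_gametolog	24.4	0.013	-2.48	100.4	0.027	-4.50
DtKita1h1_04781.t1.p1	XY_gametolog	481.9	0.093	-0.28	349.1	0.95	0.020
DtKita1h1_04763.t1.p1	XY_gametolog	526.9	0.12	-0.26	517.8	0.25	-0.55
DtKita1h1_04800.t1.p1	XY_gametolog	558.0	0.15	-0.35	774.4	0.056	-1.21
DtKita1h1_04798.t1.p1	XY_gametolog	840.0	0.24	0.16	828.7	0.57	-0.28
DtKita1h1_04750.t1.p1	XY_gametolog	689.4	0.24	-0.18	407.1	0.44	0.52
DtKita1h1_04761.t1.p1	XY_gametolog	624.1	0.45	0.14	495.9	0.65	0.13
DtKita1h1_04783.t1.p1	XY_gametolog	185.0	0.48	0.17	159.5	0.96	-0.02
DtKita1h1_04760.t1.p1	XY_gametolog	2.9	0.57	1.24	15.6	0.19	-2.64
DtKita1h1_04747.t1.p2	XY_gametolog	960.0	0.73	-0.13	705.3	0.97	0.10
DtKita1h1_04784.t1.p1	XY_gametolog	546.6	0.87	-0.04	912.0	0.0067	-1.32
DtKita1h1_04757.t1.p1	XY_gametolog	24.8	0.99	-0.01	314.5	9.60E-05	-4.41
DtKita1h1_04780.t1.p1	XY_gametolog	0.2	NA	0.92	0.8	0.78	-1.91
DtKita1h1_04789.t1	XY_gametolog	0.5	NA	-0.93	0.3	0.94	-0.56
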