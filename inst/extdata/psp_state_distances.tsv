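# title: stationary-state distance frames for the two PSP phosphoryl-transfer steps
# units: Angstrom
# note: rc1/rc2 are the tabulated reaction-coordinate values for each analysis; umbrella-sampling (us_*) rows are window means
step	method	state	rc1	rc2	ser_og_p	p_od_asp11	h_od_asp13	ser_og_h	ser_ot_h	wat_o_p	wat_o_h	h_ot_asp11
1	cpr	IM	0.73	NA	1.74	2.81	1.01	1.64	2.56	NA	NA	NA
1	cpr	TS	0.76	NA	1.83	2.71	1.23	1.20	2.74	NA	NA	NA
1	cpr	P	0.91	NA	2.76	1.78	1.79	0.99	3.13	NA	NA	NA
1	scan_1d	IM	-1.5	NA	1.72	3.25	1.03	2.44	1.54	NA	NA	NA
1	scan_1d	TS	-0.9	NA	2.04	2.94	1.60	1.02	2.84	NA	NA	NA
1	scan_1d	P	1.2	NA	3.09	1.87	1.76	0.99	3.52	NA	NA	NA
1	us_1d	IM	-1.3	NA	1.66	2.78	1.84	2.46	1.00	NA	NA	NA
1	us_1d	TS	-0.3	NA	2.36	2.54	1.71	1.01	3.02	NA	NA	NA
1	us_1d	P	1.0	NA	2.71	1.80	1.83	0.99	3.03	NA	NA	NA
1	scan_2d_op_po	IM	1.7	2.9	1.69	2.90	1.05	2.52	1.48	NA	NA	NA
1	scan_2d_op_po	TS	1.8	2.2	1.83	2.22	1.60	1.03	2.57	NA	NA	NA
1	scan_2d_op_po	P	2.8	1.8	2.80	1.79	1.78	0.99	3.18	NA	NA	NA
1	us_2d_op_po	IM	1.7	2.7	1.68	2.72	1.89	2.44	1.00	NA	NA	NA
1	us_2d_op_po	TS	2.2	2.5	2.22	2.50	1.68	1.01	2.87	NA	NA	NA
1	us_2d_op_po	P	2.7	1.8	2.71	1.80	1.83	0.99	3.03	NA	NA	NA
1	scan_2d_opo_oho	IM	-1.5	-0.7	1.74	3.24	1.00	1.70	2.38	NA	NA	NA
1	scan_2d_opo_oho	TS	-1.3	0.0	1.84	3.14	1.31	1.31	2.77	NA	NA	NA
1	scan_2d_opo_oho	P	1.2	0.7	3.09	1.87	1.75	0.97	3.50	NA	NA	NA
1	us_2d_opo_oho	IM	1.1	-0.8	1.74	2.76	1.01	1.71	2.46	NA	NA	NA
1	us_2d_opo_oho	TS	-0.6	0.3	1.94	2.63	1.54	1.04	2.72	NA	NA	NA
1	us_2d_opo_oho	P	1.0	0.8	2.78	1.78	1.79	0.97	3.11	NA	NA	NA
2	cpr	IM	0.26	NA	NA	1.74	3.50	NA	NA	3.82	0.99	4.00
2	cpr	TS	0.52	NA	NA	2.51	1.52	NA	NA	2.14	1.03	2.47
2	cpr	P	0.64	NA	NA	3.04	1.12	NA	NA	1.66	2.93	1.28
2	scan_1d	IM	-1.5	NA	NA	1.75	2.06	NA	NA	3.25	0.97	2.88
2	scan_1d	TS	1.1	NA	NA	3.04	1.57	NA	NA	1.95	1.02	2.38
2	scan_1d	P	1.6	NA	NA	3.30	1.52	NA	NA	1.68	2.90	1.02
2	us_1d	IM	-1.6	NA	NA	1.78	3.44	NA	NA	3.40	0.98	3.18
2	us_1d	TS	0.5	NA	NA	3.26	3.87	NA	NA	2.92	0.97	2.65
2	us_1d	P	1.6	NA	NA	3.26	4.33	NA	NA	1.61	3.43	1.01
2	scan_2d_op_po	IM	1.8	3.8	NA	1.79	1.73	NA	NA	3.78	0.99	3.81
2	scan_2d_op_po	TS	2.6	2.1	NA	2.60	1.61	NA	NA	2.20	1.01	2.62
2	scan_2d_op_po	P	3.2	1.8	NA	3.20	0.99	NA	NA	1.78	1.77	2.34
2	us_2d_op_po	IM	1.8	3.9	NA	1.76	4.17	NA	NA	3.61	0.98	3.33
2	us_2d_op_po	TS	2.9	2.3	NA	2.94	3.16	NA	NA	1.82	2.96	1.35
2	us_2d_op_po	P	3.1	1.7	NA	3.15	4.58	NA	NA	1.65	3.42	1.01
2	scan_2d_opo_oho	IM	-1.5	-1.0	NA	1.75	2.83	NA	NA	3.25	0.96	1.95
2	scan_2d_opo_oho	TS	1.4	-0.3	NA	3.20	1.15	NA	NA	1.76	1.35	1.62
2	scan_2d_opo_oho	P	1.5	1.0	NA	3.24	1.66	NA	NA	1.73	1.97	0.98
2	us_2d_opo_oho	IM	-1.6	-0.8	NA	1.77	1.72	NA	NA	3.40	1.00	3.41
2	us_2d_opo_oho	TS	-0.5	-0.6	NA	2.85	1.62	NA	NA	1.67	1.01	3.19
2	us_2d_opo_oho	P	1.6	0.8	NA	3.29	1.00	NA	NA	1.68	1.74	2.43
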