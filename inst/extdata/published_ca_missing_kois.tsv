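k	oases_multik	cdhit_c0.90	cdhit_c0.95	cdhit_c1.00	vmatch
19	58	108	86	33	481
21	19	55	41	9	433
23	9	37	23	3	402
25	7	44	28	4	409
27	8	45	29	5	415
29	8	53	36	7	420
31	8	47	30	8	413
33	10	43	27	9	413
35	13	51	35	8	422
37	17	60	40	10	432
39	19	57	38	9	412
41	17	59	45	9	412
43	22	63	49	14	413
45	22	67	52	14	420
47	24	76	58	19	426
49	33	81	63	25	432
51	36	89	73	28	446
53	38	95	75	33	447
55	42	100	80	35	449
57	46	103	83	37	460
59	55	113	93	42	473
61	56	112	97	43	468
63	68	125	110	52	472
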