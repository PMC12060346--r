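mirna	sex	dla	ola	aca	gac	dre	loc	phy	pfl	ame	upy	dem	count_o	count_t
miR-140-3p	female	-1.72	-1.14	-1.01	1.37	-2.43	-1.16	1.19	-2.8	.	.	3+4	5	2
miR-429a-3p	female	-3.05	-2.81	-3.05	-2.5	-2.86	1.15	.	.	.	.	3+4	5	1
miR-140-5p	female	-2	-1.55	-1.63	-1.23	-2.27	-2.36	.	.	.	.	3+4	5	0
miR-191-5p	female	-2.05	-2.07	-1.18	-1.29	-1.94	.	.	.	.	.	3+4	5	0
miR-425-5p	female	-2.88	-2	-1.12	-1.31	-2.82	.	.	.	.	.	3+4	5	0
miR-155-5p	female	-4.15	-3.82	-1.18	-1.59	-4.26	.	.	.	.	.	3+4	5	0
miR-223-3p	female	-1.11	-4.16	-1.1	-1.8	-1.56	.	.	.	.	.	1+4	5	0
miR-142-3p	female	-1.17	-1.22	-1.97	-2.99	1.86	-4.34	.	.	.	.	.	5	1
miR-34a-5p	female	-2.52	-2.2	-1.7	1.52	2.12	-2.28	-1.59	.	.	.	4	4	2
miR-148a-3p	female	-1.28	-1.45	-2.45	-2.15	1.19	-1.03	-1.45	.	.	.	3	5	1
miR-200b-3p	female	-1.88	-2.51	3.6	-2.86	-2.74	-2.47	.	.	.	.	3	4	1
miR-146a-5p	female	-1.08	-1.15	-1.65	1.29	-1.72	-2.01	-2.79	.	.	.	2	6	1
miR-192-5p	female	-2.06	-1.45	-1.32	4.91	-2.99	2.38	3.71	-2.53	.	.	2	4	3
miR-200a-3p	female	-1.48	-2.59	-3.97	3.8	-2.7	-2.27	-3.28	-3.65	.	.	.	6	1
miR-27a-3p	female	-1.11	-2.72	1.34	-1.23	1.26	-1.37	-1.56	1.68	.	.	.	5	3
miR-7132b-5p	female	-1.37	-1.23	-1.6	-2.26	-4.43	2.3	1.29	.	.	.	.	5	2
miR-200b-5p	female	-3.01	-3.38	3.16	-3.7	-4.04	-3.13	-5.36	.	.	.	.	5	1
miR-1388-3p	female	-1.4	-1.93	-2.06	-1.66	-1.51	-5.8	.	.	.	.	1	5	0
miR-33-5p	female	-1.47	-1.44	-2	1.06	2.74	3.81	-1.19	-2.45	.	.	.	4	3
miR-223-5p	female	-1.91	-3.59	-2.4	1.54	-7.07	3.75	-3.77	.	.	.	.	4	2
miR-193a-2-5p	female	-1.99	-2.83	-2.16	-4.45	-5.97	.	.	.	.	.	.	4	0
miR-143-3p	male	1.25	1.25	1.53	1.91	2.38	.	.	.	.	.	1+2+3+4	0	5
miR-129-5p	male	2.65	1.93	2.99	2.21	1.36	4.27	7.82	.	.	.	1+3+4	0	7
miR-724-5p	male	3.85	-1.98	5.4	1.83	1.1	-3.12	4.74	.	.	.	1+3+4	2	5
miR-499a-5p	male	2.23	-3.3	1.29	3.96	1.95	-1.98	2.48	2.28	3.51	.	3+4	2	7
miR-135b-5p	male	3.76	1.79	3.34	1.69	-3.76	3	5.13	4.25	.	.	3+4	1	7
miR-182a-5p	male	1.84	-1.19	2.26	3.7	-3.06	3.81	2	.	.	.	3+4	2	5
miR-7-5p	male	2.85	4.36	-3.05	1.14	1.88	3.82	.	.	.	.	3+4	1	5
miR-135b-3p	male	2.76	2.02	2.14	-2.99	1.06	5.19	.	.	.	.	3+4	1	5
miR-132b-5p	male	2.11	2.29	1.89	1.09	-2.39	-1.9	6.19	.	.	.	3	2	5
miR-2187a-5p	male	3.44	1.59	2.32	1.94	3.61	.	.	.	.	.	4	0	5
miR-212a-5p	male	2.12	3.04	-1.24	3.18	-3.36	2.81	3.39	-6.72	.	.	.	2	5
miR-15c-3p	male	1.93	-2.38	1.57	2.6	2.86	2.29	-2.77	.	.	.	.	1	5
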