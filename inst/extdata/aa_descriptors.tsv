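residue	PP1	PP2	PP3	KF1	KF2	KF3	KF4	KF5	KF6	KF7	KF8	KF9	KF10	Z1	Z2	Z3	Z4	Z5	F1	F2	F3	F4	F5	F6	T1	T2	T3	T4	T5	VHSE1	VHSE2	VHSE3	VHSE4	VHSE5	VHSE6	VHSE7	VHSE8	ProtFP1	ProtFP2	ProtFP3	ProtFP4	ProtFP5	ProtFP6	ProtFP7	ProtFP8	ST1	ST2	ST3	ST4	ST5	ST6	ST7	ST8	BLOSUM1	BLOSUM2	BLOSUM3	BLOSUM4	BLOSUM5	BLOSUM6	BLOSUM7	BLOSUM8	BLOSUM9	BLOSUM10	MSWHIM1	MSWHIM2	MSWHIM3
A	-0.96	-0.76	0.31	-1.56	-1.67	-0.97	-0.27	-0.93	-0.78	-0.2	-0.08	0.21	-0.48	0.24	-2.32	0.6	-0.14	1.3	0.3	0.62	-0.68	-0.17	0.04	-0.11	-9.11	-1.63	0.63	1.04	2.26	0.15	-1.11	-1.35	-0.92	0.02	-0.91	0.36	-0.48	-2.22	-2.31	0.46	-0.26	-1.21	0.21	0.19	0.85	-1.55	-0.79	-0.63	0.24	-0.46	-2.23	0.28	1.22	-0.57	0.39	-0.96	-0.61	-0.69	0.21	-0.48	0.47	0.06	0.46	-0.73	0.2	-0.62
C	-0.32	-0.57	-0.34	0.12	-0.89	0.45	-1.05	-0.71	2.41	1.52	-0.69	1.13	1.1	0.84	-1.67	3.71	0.18	-2.65	0.53	-0.3	-0.12	0.87	-0.47	0.19	-7.35	-0.86	-0.33	0.8	0.98	0.18	-1.67	-0.46	-0.21	0	1.2	-1.61	-0.19	1.17	-2	-1.96	2.28	1.37	-0.23	1.16	-0.06	-1.28	-0.4	0.13	0.86	-0.2	-0.72	0.64	-0.86	-1.34	0.47	-0.77	1.12	-0.7	-0.53	-0.69	-0.22	-0.42	0.07	-0.66	0.26	-0.27
D	0.82	-0.82	-0.37	0.58	-0.22	-1.58	0.81	-0.92	0.15	-1.52	0.47	0.76	0.7	3.98	0.93	1.93	-2.46	0.75	-0.87	-0.26	-0.34	0.24	0.53	-0.76	-4.65	0.75	1.39	-0.4	1.05	-1.15	0.67	-0.41	-0.01	-2.68	1.31	0.03	0.56	-2.4	1.45	-2.5	-1.26	0.54	-0.79	-0.38	0.18	-0.91	-0.05	-0.78	-0.25	1.12	0.1	-0.25	-0.08	1.17	0.01	-0.03	-0.6	0.61	0.55	-0.52	0.27	0.39	-0.05	0.11	-1	-0.96
E	0.89	-0.07	-0.46	-1.45	0.19	-1.61	1.17	-1.31	0.4	0.04	0.38	-0.35	-0.12	3.11	0.26	-0.11	-0.34	-0.25	-0.76	0.53	0.02	0.11	0.46	-0.58	-3.03	1.82	0.51	-0.58	0.43	-1.18	0.4	0.1	0.36	-2.16	-0.17	0.91	0.02	-2.64	2.04	-1.54	-1.82	0.34	0.62	0.32	0.19	-0.81	0.85	-0.52	-0.25	0.7	0.43	-0.31	0.15	1.36	-0.19	0.39	-0.59	0.53	0.35	0.22	0.27	-0.17	0.16	0.24	-0.39	-0.04
F	-0.85	0.48	-0.58	-0.21	0.98	-0.36	-1.43	0.22	-0.81	0.67	1.1	1.71	-0.44	-4.22	1.94	1.06	0.54	-0.62	0.88	0.21	0.65	-0.22	-0.37	0.28	0.49	-0.94	-0.63	-1.27	-0.44	1.52	0.61	0.96	-0.16	0.25	0.28	-1.33	-0.2	4.17	1.09	0.85	-0.3	0.68	-0.69	-0.35	-0.04	0.8	-0.69	0.76	-0.87	-0.31	0.5	-0.09	0.04	-1.01	1.13	0.55	0.73	-0.16	0.18	0.11	0.22	0.25	0.21	0.76	0.85	-0.34
G	-0.88	-1	0.49	1.46	-1.96	-0.23	-0.16	0.1	-0.11	1.32	2.36	-1.66	0.46	2.05	-4.06	0.36	-0.82	-0.38	-0.18	-0.98	-1	0.29	0.75	-0.21	-10.61	-1.21	-0.12	0.75	3.25	-0.2	-1.53	-2.63	2.28	-0.53	-1.18	2.01	-1.34	-3.82	-4.34	-1.28	0.98	-0.55	-0.31	-0.45	-0.46	-2.02	-1.57	-1.2	1	0.12	-0.82	-0.54	0.32	0.38	-1.03	-1.26	-0.58	-0.27	-0.7	-0.11	-0.74	-0.18	-0.16	-0.31	-0.28	-0.75
H	0.66	0.22	0.29	-0.41	0.52	-0.28	0.28	1.61	1.01	-1.85	0.47	1.13	1.63	2.47	1.95	0.26	3.9	0.09	-0.58	0.13	0.3	0.44	-0.11	0.48	-1.01	-1.31	0.01	-1.81	-0.21	-0.43	-0.25	0.37	0.19	0.51	1.28	0.93	0.65	0.24	1.33	0.83	1.37	-0.38	1.48	-1.54	0.02	0.34	0.58	0.72	1.11	0.54	0.43	0.21	0.33	0.64	0.94	0.63	0.27	0.45	-0.48	-0.22	-0.52	0.39	-0.38	0.84	0.67	-0.78
I	-0.94	0.31	-0.69	-0.73	-0.16	1.79	-0.77	-0.54	0.03	-0.83	0.51	0.66	-1.78	-3.89	-1.73	-1.71	-0.84	0.26	0.97	0.19	0.27	-0.32	-0.51	0.05	-4.25	-0.28	-0.15	1.4	-0.21	1.27	-0.14	0.3	-1.8	0.3	-1.61	-0.16	-0.13	3.55	-0.85	1.34	-1.09	-0.48	-0.53	0.09	0.15	-0.62	-1.03	0.85	-0.98	-0.8	-0.54	0.35	-0.33	-1.24	-0.05	1.08	-0.3	-0.73	0.21	0.47	0.26	-0.23	-0.28	-0.91	0.83	-0.25
K	0.6	0.1	0.79	-0.34	0.82	-0.23	1.7	1.54	-1.62	1.15	-0.08	-0.48	0.6	2.29	0.89	-2.49	1.49	0.31	-0.81	0.33	0.26	0.05	0.45	0.6	-2.59	2.34	-1.69	0.41	-0.21	-1.17	0.7	0.7	0.8	1.64	0.67	1.63	0.13	-2.61	2.54	0.42	0.78	1.05	-0.56	0.19	-0.39	-0.04	1.24	-0.7	0.8	-0.47	0.41	0.76	-0.44	1.17	0.28	0.3	-0.25	0.4	-0.11	0.72	0.05	-0.49	0.35	-0.51	0.08	0.6
L	-0.9	0.49	-0.66	-1.04	0	-0.24	-1.1	-0.55	-2.05	0.96	-0.76	0.45	0.93	-4.28	-1.3	-1.49	-0.72	0.84	0.92	0.52	0.28	-0.33	-0.44	0.04	-4.38	0.28	-0.49	1.45	0.02	1.36	0.07	0.26	-0.8	0.22	-1.37	0.08	-0.62	3.16	-0.21	0.97	-1.16	0.32	0.26	0.46	0.52	-0.55	-1.05	0.63	-0.83	-0.53	0	0.49	0.42	-1.1	0	1.02	-0.4	-0.55	0.18	0.39	-0.04	0.27	0.44	-0.74	0.72	-0.16
M	-0.82	0.21	-0.51	-1.4	0.18	-0.42	-0.73	2	1.52	0.26	0.11	-1.27	0.27	-2.85	-0.22	0.47	1.94	-0.98	0.66	0.54	0.34	0.21	-0.28	0.11	-4.08	0.98	-2.34	1.64	-0.79	1.01	-0.53	0.43	0	0.23	0.1	-0.86	-0.68	2.35	0.37	0.16	0.55	2.08	0.89	-0.74	0.16	-0.46	-0.45	0.37	0.33	0.29	1.03	-0.49	-0.27	-0.87	0.22	0.91	0.08	0.19	0.39	-0.34	-0.09	-0.41	-0.44	-0.7	1	-0.32
N	0.82	-0.57	-0.48	1.14	-0.07	-0.12	0.81	0.18	0.37	-0.09	1.23	1.1	-1.73	3.05	1.62	1.04	-1.15	1.61	-0.71	-0.39	-0.18	0.38	0.42	-0.26	-4.62	0.66	1.16	-0.22	0.93	-0.99	0	-0.37	0.69	-0.55	0.85	0.73	-0.8	-2.72	0.61	-1.34	-0.29	0.26	-0.7	-0.51	-0.29	-0.89	-0.06	-0.65	-0.21	0.92	0.16	-0.14	-0.17	1	0.13	-0.42	-0.32	0.61	0.12	-0.09	0.07	0.4	0.11	0.14	0.2	-0.66
P	-0.81	-0.35	-0.31	2.06	-0.33	-1.15	-0.75	0.88	-0.45	0.3	-2.3	0.74	-0.28	-1.66	0.27	1.84	0.7	2	-0.33	-0.95	-0.45	0.16	0.38	-0.12	-5.11	-3.54	-0.53	-0.36	-0.29	0.22	-0.17	-0.5	0.05	-0.01	-1.34	-0.19	3.56	-1.99	-0.68	-0.29	-1.21	-2.49	-1.8	0.13	-0.26	-1.58	0.37	-1.05	-0.43	-0.93	0.55	-0.16	0.26	0.37	-0.78	-0.46	-0.98	0.21	-0.68	0.35	0.54	-0.26	0.39	-0.43	0.73	-0.6
Q	0.78	-0.3	-0.38	-0.47	0.24	0.07	1.1	1.1	0.59	0.84	-0.71	-0.03	-2.33	1.75	0.5	-1.44	-1.34	0.66	-0.61	0.36	0.08	0.14	0.31	-0.09	-3	1.72	0.28	-0.39	0.33	-0.96	0.12	0.18	0.16	0.09	0.42	-0.2	-0.41	-2.05	1.32	-0.75	-0.54	0.66	0.39	-0.5	-0.58	-0.39	0.65	-0.1	-0.34	0.76	-0.16	-0.17	0.4	1.05	0.22	0.32	-0.29	0.45	0.08	0.48	0.15	0.1	-0.27	0.3	1	-0.3
R	0.8	0.63	0.99	0.22	1.27	1.37	1.87	-1.7	0.46	0.92	-0.39	0.23	0.93	3.52	2.5	-3.5	1.99	-0.17	-0.95	0.29	0.57	0.36	0.24	0.82	0.23	3.89	-1.16	-0.39	-0.06	-1.47	1.45	1.24	1.27	1.55	1.47	1.3	0.83	-1.98	2.47	1.62	1.36	-0.49	0.2	0.81	0.56	-0.06	0.73	-0.01	-0.1	-0.25	0.3	1.26	0.85	0.98	0.57	0.39	-0.14	0.37	-0.42	0.77	-0.14	0.17	-0.16	-0.22	0.27	1
S	0.41	-0.82	0.57	0.81	-1.08	0.16	0.42	-0.21	-0.43	-1.89	-1.15	-0.97	-0.23	2.39	-1.07	1.15	-1.39	0.67	-0.25	-0.34	-0.62	0.26	0.48	-0.14	-7.44	-0.65	0.68	-0.17	1.58	-0.67	-0.86	-1.07	-0.41	-0.32	0.27	-0.64	0.11	-2.78	-1.78	-1.02	0.12	0.32	0.23	-0.49	0.31	-1.34	-0.52	-0.73	-0.04	0.45	-0.93	-0.45	0.12	0.43	-0.33	-0.82	-0.33	0.06	0.38	-0.3	0.16	-0.42	-0.15	-0.8	0.61	-1
T	0.4	-0.64	0.37	0.26	-0.7	1.21	0.63	-0.1	0.21	0.24	-1.15	-0.56	0.19	0.75	-2.18	-1.12	-1.46	-0.4	-0.18	-0.24	-0.34	0.12	0.25	-0.06	-5.97	-0.62	1.11	0.31	0.95	-0.34	-0.51	-0.55	-1.06	-0.06	-0.01	-0.79	0.39	-1.54	-1.06	-0.12	-0.42	0.18	0.44	-0.41	0.29	-1.06	-0.6	-0.33	-0.2	0.13	-0.57	-0.13	0.19	0.09	-0.35	-0.36	-0.33	-0.28	0.46	-0.21	0.2	-0.06	-0.34	-0.58	0.85	-0.89
V	-1	0.13	-0.71	-0.74	-0.71	2.04	-0.4	0.5	-0.81	-1.07	0.06	-0.46	0.65	-2.59	-2.64	-1.54	-0.85	-0.02	0.89	0.12	0.03	-0.29	-0.49	0.01	-5.87	-0.94	0.28	1.1	0.48	0.76	-0.92	-0.17	-1.91	0.22	-1.4	-0.24	-0.03	2.47	-1.33	1.32	-1.11	-0.81	-0.35	-0.4	-0.09	-0.94	-1.13	0.63	-0.93	-0.69	-1.04	0.43	-0.1	-1.08	-0.24	0.82	-0.47	-0.75	0.38	0.25	0.38	-0.08	-0.04	-1	0.79	-0.58
W	-0.83	1	-0.4	0.3	2.1	-0.72	-1.57	-1.16	0.57	-0.48	-0.4	-2.3	-0.6	-4.36	3.94	0.59	3.44	-1.59	0.51	0.24	1	0.1	-0.52	0.43	5.73	-2.67	-0.07	-1.96	-0.54	1.5	2.06	1.79	0.75	0.75	-0.13	-1.01	-0.85	4.38	2.09	0.24	0.73	-0.56	0.19	1	-0.69	1.86	0.11	1.07	-0.77	0.27	1.15	0.44	0.1	-0.6	1.38	0.44	1.1	0.17	-0.38	-0.31	-0.1	-0.39	0.26	1	0.98	-0.47
Y	-0.41	0.74	-0.23	1.38	1.48	0.8	-0.56	0	-0.68	-0.31	1.03	-0.05	0.53	-2.54	2.44	0.43	0.04	-1.47	0.28	-0.01	0.67	0.02	-0.33	0.31	2.08	-0.47	0.07	-1.67	-0.35	0.61	1.6	1.17	0.73	0.53	0.25	-0.96	-0.52	2.49	1.85	0.28	0.76	-0.62	-0.46	-0.52	-0.46	1.1	-0.49	0.83	-0.32	0.1	0.65	-0.29	-0.21	-0.42	1.25	0.38	0.66	0.25	-0.13	-0.18	-0.12	0.48	-0.25	0.97	0.66	-0.16
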