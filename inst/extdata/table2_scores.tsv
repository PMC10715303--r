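variant	ddg_fold_alamut	as_printed_alamut	ddg_fold_foldx	as_printed_foldx	ddg_fold_charmm	as_printed_charmm	ddg_binding_h3k4	as_printed_h3k4	ddg_binding_sah	as_printed_sah	delta_frustration	as_printed_frustration
Q4761R	0.0	Neutral	-0.78	Stabilizing	-0.12	Neutral	0.12	Neutral	0.08	Neutral	-0.07	Neutral
R4763Q	-0.2	Neutral	-0.64	Stabilizing	-0.02	Neutral	-0.12	Neutral	-0.05	Neutral	0.48	Neutral
S4778C	-0.2	Neutral	5.40	Destabilizing	1.24	Destabilizing	-0.06	Neutral	-0.04	Neutral	1.69	MinimallyFrustrated
R4779H	-0.6	Stabilizing	0.21	Neutral	0.91	Destabilizing	-0.18	Neutral	-0.26	Neutral	-0.71	Neutral
E4792D	0.2	Neutral	-0.35	Neutral	0.93	Destabilizing	-0.01	Neutral	0	Neutral	0.64	Neutral
V4797F	0.0	Neutral	8.89	Destabilizing	-0.13	Neutral	-0.03	Neutral	-0.01	Neutral	0.32	Neutral
E4799K	0.3	Neutral	2.04	Destabilizing	4.13	Destabilizing	0.45	Neutral	0.1	Neutral	-0.29	Neutral
G4802R	0.0	Neutral	31.81	Destabilizing	12.37	Destabilizing	0.97	Destabilizing	-0.03	Neutral	-0.18	Neutral
I4805V	0.1	Neutral	1.03	Destabilizing	1.25	Destabilizing	0.08	Neutral	0	Neutral	-0.24	Neutral
R4806Q	-0.3	Neutral	-0.13	Neutral	-0.59	Stabilizing	-0.21	Neutral	-0.04	Neutral	-1.62	HighlyFrustrated
R4806W	-0.3	Neutral	0.41	Neutral	-1.15	Stabilizing	-0.19	Neutral	-0.04	Neutral	-0.94	Neutral
E4808K	0.6	Destabilizing	1.13	Destabilizing	1.04	Destabilizing	0.77	Destabilizing	0.11	Neutral	-1.70	HighlyFrustrated
N4811S	0.4	Neutral	0.23	Neutral	0.8	Destabilizing	0.71	Destabilizing	0.01	Neutral	0.02	Neutral
R4828H	-0.2	Neutral	6.06	Destabilizing	1.17	Destabilizing	0.94	Destabilizing	-0.1	Neutral	-0.42	Neutral
T4838M	-0.1	Neutral	0.62	Destabilizing	0.91	Destabilizing	-0.21	Neutral	-0.03	Neutral	-0.72	Neutral
R4845K	-0.2	Neutral	-0.86	Stabilizing	1.61	Destabilizing	-0.2	Neutral	0.49	Neutral	-0.40	Neutral
R4845S	-0.2	Neutral	2.31	Destabilizing	2.33	Destabilizing	-0.34	Neutral	0.22	Neutral	0.52	Neutral
R4845W	-0.2	Neutral	6.29	Destabilizing	0.88	Destabilizing	-0.72	Stabilizing	0.4	Neutral	1.91	Neutral
C4851Y	4.6	Destabilizing	9.23	Destabilizing	3.46	Destabilizing	0.23	Neutral	4.9	Destabilizing	-1.85	HighlyFrustrated
N4854D	0.0	Neutral	2.23	Destabilizing	1.76	Destabilizing	-0.2	Neutral	-0.2	Neutral	-0.18	Neutral
C4855Y	0.0	Neutral	5.52	Destabilizing	-0.93	Stabilizing	0.01	Neutral	-0.01	Neutral	-0.72	Neutral
V4860A	0.0	Neutral	2.77	Destabilizing	1.35	Destabilizing	0.01	Neutral	0	Neutral	-0.98	Neutral
F4862L	0.0	Neutral	1.56	Destabilizing	1.28	Destabilizing	0.02	Neutral	0	Neutral	1.91	MinimallyFrustrated
I4870S	0.1	Neutral	5.99	Destabilizing	3.96	Destabilizing	0.07	Neutral	0.01	Neutral	-2.15	HighlyFrustrated
R4874W	-0.4	Neutral	1.84	Destabilizing	0.75	Destabilizing	-0.17	Neutral	-0.2	Neutral	-2.45	HighlyFrustrated
E4881D	0.3	Neutral	3.18	Destabilizing	3.05	Destabilizing	0.03	Neutral	-0.01	Neutral	0.44	Neutral
Y4884C	0.8	Destabilizing	2.65	Destabilizing	3.47	Destabilizing	0.76	Destabilizing	0	Neutral	0.92	MinimallyFrustrated
F4890Y	1.1	Destabilizing	0.44	Neutral	-0.59	Stabilizing	-0.17	Neutral	-0.01	Neutral	-2.26	HighlyFrustrated
D4892G	0.5	Destabilizing	-1.17	Stabilizing	-1.3	Stabilizing	0.38	Neutral	0.14	Neutral	0.69	Neutral
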