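ts_min	t_min	gamma_per_h	vp_class	size_class	kappa_bar	xi_bar
1	6	0	1	fine	0.38	0.65
1	6	0	1	coarse	0.03	0.34
1	6	0	2	fine	0.61	0.73
1	6	0	2	coarse	0.09	0.36
1	6	0	3	fine	0.69	0.84
1	6	0	3	coarse	0.16	0.43
1	6	10	1	fine	0.4	0.65
1	6	10	1	coarse	0.03	0.34
1	6	10	2	fine	0.61	0.73
1	6	10	2	coarse	0.1	0.36
1	6	10	3	fine	0.7	0.84
1	6	10	3	coarse	0.17	0.43
1	6	20	1	fine	0.41	0.65
1	6	20	1	coarse	0.04	0.34
1	6	20	2	fine	0.62	0.73
1	6	20	2	coarse	0.1	0.36
1	6	20	3	fine	0.71	0.84
1	6	20	3	coarse	0.18	0.43
10	15	0	1	fine	0.35	0.65
10	15	0	1	coarse	0.02	0.34
10	15	0	2	fine	0.59	0.73
10	15	0	2	coarse	0.08	0.36
10	15	0	3	fine	0.66	0.84
10	15	0	3	coarse	0.13	0.43
10	15	10	1	fine	0.38	0.65
10	15	10	1	coarse	0.03	0.34
10	15	10	2	fine	0.6	0.73
10	15	10	2	coarse	0.09	0.36
10	15	10	3	fine	0.68	0.84
10	15	10	3	coarse	0.15	0.43
10	15	20	1	fine	0.4	0.65
10	15	20	1	coarse	0.04	0.34
10	15	20	2	fine	0.62	0.73
10	15	20	2	coarse	0.1	0.36
10	15	20	3	fine	0.7	0.84
10	15	20	3	coarse	0.17	0.43
10	60	0	1	fine	0.27	0.65
10	60	0	1	coarse	0.01	0.34
10	60	0	2	fine	0.45	0.73
10	60	0	2	coarse	0.04	0.36
10	60	0	3	fine	0.48	0.84
10	60	0	3	coarse	0.05	0.43
10	60	5	1	fine	0.32	0.65
10	60	5	1	coarse	0.02	0.34
10	60	5	2	fine	0.54	0.73
10	60	5	2	coarse	0.06	0.36
10	60	5	3	fine	0.59	0.84
10	60	5	3	coarse	0.1	0.43
10	60	10	1	fine	0.36	0.65
10	60	10	1	coarse	0.03	0.34
10	60	10	2	fine	0.58	0.73
10	60	10	2	coarse	0.08	0.36
10	60	10	3	fine	0.65	0.84
10	60	10	3	coarse	0.13	0.43
10	60	20	1	fine	0.4	0.65
10	60	20	1	coarse	0.04	0.34
10	60	20	2	fine	0.61	0.73
10	60	20	2	coarse	0.1	0.36
10	60	20	3	fine	0.7	0.84
10	60	20	3	coarse	0.17	0.43
60	65	0	1	fine	0.29	0.65
60	65	0	1	coarse	0.01	0.34
60	65	0	2	fine	0.49	0.73
60	65	0	2	coarse	0.04	0.36
60	65	0	3	fine	0.52	0.84
60	65	0	3	coarse	0.06	0.43
60	65	5	1	fine	0.33	0.65
60	65	5	1	coarse	0.02	0.34
60	65	5	2	fine	0.55	0.73
60	65	5	2	coarse	0.07	0.36
60	65	5	3	fine	0.61	0.84
60	65	5	3	coarse	0.1	0.43
60	65	10	1	fine	0.36	0.65
60	65	10	1	coarse	0.03	0.34
60	65	10	2	fine	0.59	0.73
60	65	10	2	coarse	0.08	0.36
60	65	10	3	fine	0.66	0.84
60	65	10	3	coarse	0.13	0.43
60	65	20	1	fine	0.4	0.65
60	65	20	1	coarse	0.04	0.34
60	65	20	2	fine	0.62	0.73
60	65	20	2	coarse	0.1	0.36
60	65	20	3	fine	0.7	0.84
60	65	20	3	coarse	0.17	0.43
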