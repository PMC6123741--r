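group	scenario	gene_flow	k	lnL	AIC	dAIC	weight	boot_prop
Decim	S1	none	9	-9159.70	18337.398	55.89	5.7e-13	0.00
Decim	S1	past_and_recent	19	-9129.30	18296.592	15.08	0.0004	0.01
Decim	S1	recent	15	-9125.76	18281.512	0.00	0.7806	0.92
Decim	S2	none	9	-9211.42	18440.838	159.33	2.0e-35	0.00
Decim	S2	past_and_recent	19	-9128.76	18295.514	14.00	0.0007	0.00
Decim	S2	recent	15	-9129.98	18289.966	8.45	0.0114	0.05
Decim	S3	none	9	-9150.28	18318.564	37.05	7.0e-09	0.00
Decim	S3	past_and_recent	19	-9127.59	18293.174	11.66	0.0023	0.00
Decim	S3	recent	15	-9127.10	18284.19	2.68	0.2046	0.02
Cassini	S1	none	9	-7977.40	15972.792	360.83	2.7e-79	0.08
Cassini	S1	past_and_recent	19	-7789.05	15616.092	4.13	0.0770	0.02
Cassini	S1	recent	15	-7790.98	15611.962	0.00	0.6068	0.75
Cassini	S2	none	9	-8199.22	16416.44	804.48	1.2e-175	0.01
Cassini	S2	past_and_recent	19	-7792.81	15623.612	11.65	0.0018	0.00
Cassini	S2	recent	15	-7792.62	15615.234	3.27	0.1182	0.08
Cassini	S3	none	9	-7849.35	15716.701	104.73	1.1e-23	0.03
Cassini	S3	past_and_recent	19	-7792.77	15623.538	11.58	0.0019	0.00
Cassini	S3	recent	15	-7792.12	15614.238	2.28	0.1944	0.03
Decula	S1	none	9	-6272.00	12562.006	1095.14	5.9065e-239	0.00
Decula	S1	past_and_recent	19	-5717.92	11473.838	6.97	0.0116	0.00
Decula	S1	recent	15	-5718.67	11467.338	0.47	0.2989	0.32
Decula	S2	none	9	-6208.73	12435.464	968.60	1.7765e-211	0.00
Decula	S2	past_and_recent	19	-5718.51	11475.01	8.14	0.0064	0.00
Decula	S2	recent	15	-5718.66	11467.314	0.45	0.3025	0.22
Decula	S3	none	9	-6098.49	12214.987	748.11	1.3399e-163	0.00
Decula	S3	past_and_recent	19	-5719.41	11476.816	9.95	0.0026	0.00
Decula	S3	recent	15	-5718.43	11466.868	0.00	0.3780	0.46
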