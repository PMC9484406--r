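patient_id	sex	age_at_onset	goldman_score	rs429358_gt	rs7412_gt	ptau_ab42_ratio	ab42_ab40_ratio
AD#001	F	54	3.5	T/T	C/C	0.182	0.429
AD#002	F	57	3.5	C/T	C/C	0.336	0.493
AD#003	M	56	3.5	T/T	C/C	0.199	0.345
AD#004	F	59	0	C/T	C/C	0.174	0.521
AD#005	F	64	3.5	T/T	C/C	0.172	0.403
AD#006	M	59	0	T/T	C/C	0.205	0.536
AD#007	F	55	0	T/T	C/C	0.182	0.471
AD#008	F	61	2	T/T	C/T	0.206	0.517
AD#009	F	58	0	C/T	C/C	0.274	0.555
AD#010	M	58	3.5	T/T	C/C	0.126	0.402
AD#011	M	55	0	C/T	C/C	0.311	0.367
AD#012	F	57	1	T/T	C/C	0.298	0.588
AD#013	M	59	1	T/T	C/C	0.126	0.536
AD#014	F	64	0	C/T	C/C	0.239	0.373
AD#015	M	59	2	T/T	C/C	0.178	0.528
AD#016	F	63	1	C/T	C/C	0.306	0.375
AD#017	F	64	3.5	T/T	C/C	0.275	0.331
AD#018	F	59	2	C/T	C/C	0.284	0.48
AD#019	M	64	0	C/T	C/C	0.185	0.442
AD#020	M	64	0	T/T	C/C	0.32	0.36
AD#021	M	57	0	C/T	C/C	0.168	0.512
AD#022	F	57	0	T/T	C/C	0.232	0.5
AD#023	F	52	0	T/T	C/C	0.238	0.396
AD#024	M	56	0	T/T	C/C	0.329	0.423
AD#025	F	60	1.5	T/T	C/C	0.286	0.492
AD#026	F	64	3	T/T	C/C	0.168	0.556
AD#027	M	61	0	T/T	C/C	0.234	0.36
AD#028	F	56	3.5	T/T	C/C	0.163	0.592
AD#029	M	60	3.5	C/T	C/C	0.33	0.445
AD#030	F	59	0	T/T	C/C	0.16	0.403
AD#031	F	45	0	T/T	C/C	0.187	0.535
AD#032	M	56	3.5	T/T	C/C	0.187	0.595
AD#033	F	57	1.5	C/C	C/C	0.19	0.417
AD#034	M	55	0	T/T	C/C	0.16	0.501
AD#035	F	40	3	C/T	C/C	0.2	0.404
AD#036	M	59	3	C/C	C/C	0.284	0.475
AD#037	M	54	2	C/T	C/T	0.285	0.425
AD#038	M	60	0	T/T	C/C	0.204	0.571
AD#039	F	59	0	T/T	C/C	0.334	0.412
AD#040	M	48	2	C/C	C/C	0.309	0.323
AD#041	M	52	3.5	T/T	C/C	0.268	0.417
AD#042	F	54	0	C/T	C/C	0.204	0.541
AD#043	M	53	0	T/T	C/C	0.32	0.535
AD#044	F	48	0	C/T	C/C	0.202	0.458
AD#045	F	50	0	C/C	C/C	0.274	0.379
AD#046	M	55	3.5	C/C	C/C	0.317	0.466
AD#047	M	61	0	T/T	C/C	0.254	0.338
AD#048	F	64	2	C/T	C/C	0.19	0.333
AD#049	F	55	3.5	C/T	C/C	0.231	0.403
AD#050	M	48	0	T/T	C/C	0.263	0.518
AD#051	F	64	0	T/T	C/C	0.213	0.49
AD#052	M	55	3.5	C/C	C/C	0.209	0.456
AD#053	M	57	0	T/T	C/C	0.328	0.566
AD#054	M	64	1.5	T/T	C/C	0.186	0.456
AD#055	M	50	1.5	T/T	C/C	0.247	0.503
AD#056	F	57	0	T/T	C/C	0.185	0.548
AD#057	F	61	3.5	C/T	C/C	0.136	0.527
AD#058	F	54	0	T/T	C/C	0.241	0.41
AD#059	F	51	2	T/T	C/C	0.193	0.423
AD#060	M	51	0	T/T	C/T	0.133	0.551
AD#061	F	53	0	C/T	C/C	0.289	0.498
AD#062	F	60	0	T/T	C/C	0.218	0.365
AD#063	F	46	0	T/T	C/C	0.2	0.389
AD#064	F	62	0	T/T	C/C	0.316	0.514
AD#065	F	48	3.5	T/T	C/C	0.248	0.422
AD#066	M	62	0	T/T	C/C	0.218	0.432
AD#067	M	50	0	T/T	C/C	0.332	0.549
AD#068	F	61	0	C/T	C/C	0.182	0.336
AD#069	M	51	0	T/T	C/C	0.234	0.566
AD#070	F	49	1	T/T	C/C	0.326	0.526
AD#071	M	56	3	T/T	C/C	0.338	0.399
AD#072	M	54	3	T/T	C/C	0.233	0.516
AD#073	M	53	0	C/T	C/C	0.343	0.437
AD#074	F	53	3.5	C/T	C/C	0.344	0.354
AD#075	F	51	0	T/T	C/C	0.308	0.326
AD#076	M	51	0	C/T	C/C	0.349	0.544
AD#077	M	64	0	T/T	C/C	0.278	0.571
AD#078	M	63	0	T/T	C/C	0.258	0.353
AD#079	F	59	1.5	C/C	C/C	0.209	0.442
AD#080	M	57	0	C/T	C/C	0.146	0.462
AD#081	M	50	0	T/T	C/C	0.237	0.549
AD#082	M	56	0	T/T	C/C	0.222	0.444
AD#083	F	64	0	C/T	C/C	0.308	0.302
AD#084	F	58	0	T/T	C/C	0.271	0.545
AD#085	F	59	0	T/T	C/C	0.193	0.455
AD#086	F	47	1.5	T/T	C/C	0.16	0.575
AD#087	M	46	0	T/T	C/C	0.305	0.451
AD#088	M	59	0	T/T	C/C	0.233	0.477
AD#089	F	55	3.5	T/T	C/C	0.273	0.579
AD#090	M	64	0	T/T	C/C	0.294	0.584
AD#091	F	52	3.5	T/T	C/C	0.209	0.387
AD#092	M	58	3.5	T/T	C/C	0.237	0.526
AD#093	F	48	3.5	C/C	C/C	0.174	0.357
AD#094	F	44	3.5	C/T	C/C	0.249	0.305
AD#095	F	50	0	C/T	C/C	0.302	0.414
AD#096	F	59	0	T/T	C/C	0.302	0.569
AD#097	M	64	0	C/T	C/C	0.142	0.343
AD#098	M	55	0	C/T	C/T	0.34	0.304
AD#099	M	64	0	C/T	C/C	0.281	0.33
AD#100	M	60	3	C/T	C/C	0.341	0.58
AD#101	M	49	3.5	C/T	C/C	0.149	0.531
AD#102	F	56	3.5	C/T	C/C	0.196	0.532
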