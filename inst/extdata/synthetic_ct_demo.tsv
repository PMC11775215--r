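sample_id	group	tissue	gene	ct_rep1	ct_rep2
WT_1	control_wt	head_kidney	Ef1a	19.7	19.74
WT_1	control_wt	head_kidney	mIgM	23.78	23.78
WT_1	control_wt	head_kidney	sIgM	22.25	22.27
WT_1	control_wt	head_kidney	IgT	26.8	26.98
WT_2	control_wt	head_kidney	Ef1a	19.82	19.95
WT_2	control_wt	head_kidney	mIgM	24.09	24.14
WT_2	control_wt	head_kidney	sIgM	22.08	22.07
WT_2	control_wt	head_kidney	IgT	26.35	26.14
WT_3	control_wt	head_kidney	Ef1a	19.46	19.51
WT_3	control_wt	head_kidney	mIgM	24.13	24.19
WT_3	control_wt	head_kidney	sIgM	21.75	21.7
WT_3	control_wt	head_kidney	IgT	25.94	25.93
Alb_1	control_albino	head_kidney	Ef1a	19.26	19.34
Alb_1	control_albino	head_kidney	mIgM	24.21	24.05
Alb_1	control_albino	head_kidney	sIgM	21.8	21.87
Alb_1	control_albino	head_kidney	IgT	25.97	25.91
Alb_2	control_albino	head_kidney	Ef1a	19.11	19.01
Alb_2	control_albino	head_kidney	mIgM	24.03	24.13
Alb_2	control_albino	head_kidney	sIgM	22.29	22.13
Alb_2	control_albino	head_kidney	IgT	26.12	26.04
Alb_3	control_albino	head_kidney	Ef1a	19.04	19.07
Alb_3	control_albino	head_kidney	mIgM	24.27	24.34
Alb_3	control_albino	head_kidney	sIgM	22.36	22.37
Alb_3	control_albino	head_kidney	IgT	26.28	26.17
IgM_15	crispant	head_kidney	Ef1a	18.72	18.65
IgM_15	crispant	head_kidney	mIgM	25.96	25.99
IgM_15	crispant	head_kidney	sIgM	21.87	21.71
IgM_15	crispant	head_kidney	IgT	24.8	24.77
IgM_16	crispant	head_kidney	Ef1a	18.7	18.69
IgM_16	crispant	head_kidney	mIgM	26.25	26.44
IgM_16	crispant	head_kidney	sIgM	22.22	22.32
IgM_16	crispant	head_kidney	IgT	24.95	24.84
IgM_17	crispant	head_kidney	Ef1a	19.27	19.36
IgM_17	crispant	head_kidney	mIgM	26.49	26.49
IgM_17	crispant	head_kidney	sIgM	21.58	21.7
IgM_17	crispant	head_kidney	IgT	24.32	24.32
IgM_18	crispant	head_kidney	Ef1a	19.3	19.26
IgM_18	crispant	head_kidney	mIgM	26.71	26.71
IgM_18	crispant	head_kidney	sIgM	21.51	21.29
IgM_18	crispant	head_kidney	IgT	25.26	25.21
IgM_19	crispant	head_kidney	Ef1a	18.58	18.51
IgM_19	crispant	head_kidney	mIgM	26.5	26.56
IgM_19	crispant	head_kidney	sIgM	21.88	21.76
IgM_19	crispant	head_kidney	IgT	25.11	25.22
IgM_20	crispant	head_kidney	Ef1a	19.33	19.39
IgM_20	crispant	head_kidney	mIgM	26.27	26.31
IgM_20	crispant	head_kidney	sIgM	21.88	21.68
IgM_20	crispant	head_kidney	IgT	24.51	24.51
WT_1	control_wt	spleen	Ef1a	19.96	19.9
WT_1	control_wt	spleen	mIgM	25	24.88
WT_1	control_wt	spleen	sIgM	22.76	22.6
WT_1	control_wt	spleen	IgT	26.78	26.66
WT_2	control_wt	spleen	Ef1a	19.34	19.34
WT_2	control_wt	spleen	mIgM	24.82	24.8
WT_2	control_wt	spleen	sIgM	22.86	22.89
WT_2	control_wt	spleen	IgT	26.71	26.74
WT_3	control_wt	spleen	Ef1a	19.76	19.72
WT_3	control_wt	spleen	mIgM	25.06	24.87
WT_3	control_wt	spleen	sIgM	23.04	23.07
WT_3	control_wt	spleen	IgT	27.28	27.22
Alb_1	control_albino	spleen	Ef1a	20.75	20.66
Alb_1	control_albino	spleen	mIgM	24.77	24.69
Alb_1	control_albino	spleen	sIgM	23.2	23.02
Alb_1	control_albino	spleen	IgT	26.4	26.65
Alb_2	control_albino	spleen	Ef1a	19.61	19.69
Alb_2	control_albino	spleen	mIgM	24.85	24.92
Alb_2	control_albino	spleen	sIgM	22.65	22.76
Alb_2	control_albino	spleen	IgT	27.1	27.15
Alb_3	control_albino	spleen	Ef1a	20.13	20.18
Alb_3	control_albino	spleen	mIgM	24.82	25.03
Alb_3	control_albino	spleen	sIgM	22.68	22.75
Alb_3	control_albino	spleen	IgT	26.53	26.72
IgM_15	crispant	spleen	Ef1a	19.76	19.67
IgM_15	crispant	spleen	mIgM	27.13	27.04
IgM_15	crispant	spleen	sIgM	22.87	22.79
IgM_15	crispant	spleen	IgT	26.03	25.97
IgM_16	crispant	spleen	Ef1a	19.51	19.74
IgM_16	crispant	spleen	mIgM	27.12	27.1
IgM_16	crispant	spleen	sIgM	22.91	23.03
IgM_16	crispant	spleen	IgT	25.61	25.57
IgM_17	crispant	spleen	Ef1a	19.67	19.58
IgM_17	crispant	spleen	mIgM	27.81	28
IgM_17	crispant	spleen	sIgM	22.28	22.14
IgM_17	crispant	spleen	IgT	25.76	25.64
IgM_18	crispant	spleen	Ef1a	19.31	19.3
IgM_18	crispant	spleen	mIgM	27.04	27.23
IgM_18	crispant	spleen	sIgM	22.51	22.43
IgM_18	crispant	spleen	IgT	25.28	25.14
IgM_19	crispant	spleen	Ef1a	20.16	20.07
IgM_19	crispant	spleen	mIgM	27.24	27.42
IgM_19	crispant	spleen	sIgM	22.81	22.77
IgM_19	crispant	spleen	IgT	25.23	25.42
IgM_20	crispant	spleen	Ef1a	20.18	20.24
IgM_20	crispant	spleen	mIgM	27.91	27.79
IgM_20	crispant	spleen	sIgM	21.94	21.99
IgM_20	crispant	spleen	IgT	25.43	25.46
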