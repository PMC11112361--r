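state_id	log2_fc	ttest_p	n_detected	pct_detected	auc	roc_p	paralog_shared
ERK2 (T185)	1.10	0.001	32	100	0.847	0.0008	FALSE
MARK1 (S219)	0.75	0.001	26	81.3	0.866	0.0013	TRUE
RSK1 (T573)	0.89	0.003	32	100	0.792	0.0049	TRUE
CaMK1D (T180)	1.15	0.007	28	87.5	0.797	0.0081	FALSE
ERK1 (T202)	0.72	0.008	32	100	0.741	0.0202	FALSE
FAK (Y576)	-0.64	0.009	22	68.8	0.818	0.0115	FALSE
p38A (T180)	0.78	0.010	26	81.3	0.764	0.0240	FALSE
MARK1 (T214)	1.10	0.013	13	40.6	0.762	0.1161	TRUE
CaMKIV (S189)	0.42	0.026	24	75	0.748	0.0397	TRUE
p38A (T180 + Y182)	0.54	0.031	29	90.6	0.733	0.0325	FALSE
PAK4 (S474)	0.57	0.046	32	100	0.694	0.0616	FALSE
DDR1 (Y796)	-2.22	0.049	7	21.9	1.000	0.0339	FALSE
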