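edge	med_sch_mean	med_sch_sd	med_hc_mean	med_hc_sd	med_p	med_t	fes_mean	fes_sd	fes_hc_mean	fes_hc_sd	fes_p	fes_t
Frontal_Sup_R-Frontal_Mid_R	1.42	0.37	1.55	0.32	<0.001	-3.76	1.33	0.36	0.78	0.39	<0.001	7.64
Supp_Motor_Area_L-Supp_Motor_Area_R	1.82	0.37	1.91	0.39	0.012	-2.55	1.71	0.42	1.70	0.50	<0.001	5.31
Insula_L-Insula_R	1.43	0.43	1.61	0.39	<0.001	-3.61	1.16	0.40	1.07	0.32	-	-
Cuneus_L-Cuneus_R	1.49	0.36	1.66	0.47	0.001	-2.62	1.53	0.45	1.50	0.39	-	-
Precentral_R-Postcentral_R	1.42	0.40	1.55	0.38	0.009	-2.64	1.26	0.37	0.94	0.49	<0.001	3.78
Postcentral_L-Postcentral_R	1.33	0.46	1.53	0.42	0.001	-3.28	1.28	0.35	0.96	0.47	<0.001	4.16
Precuneus_L-Precuneus_R	1.90	0.36	2.14	0.32	<0.001	-4.50	1.67	0.33	1.62	0.40	-	-
Temporal_Mid_L-Temporal_Mid_R	1.21	0.31	1.36	0.40	0.009	-2.66	1.08	0.39	1.22	0.40	-	-
Frontal_Sup_L-Frontal_Sup_R	1.43	0.38	1.50	0.43	-	-	1.36	0.46	0.56	0.43	<0.001	9.45
Frontal_Sup_Medial_L-Frontal_Sup_Medial_R	1.69	0.42	1.75	0.45	-	-	1.50	0.36	0.82	0.40	<0.001	9.24
Lingual_L-Fusiform_L	1.32	0.35	1.31	0.35	-	-	1.18	0.40	0.88	0.34	<0.001	4.03
Lingual_R-Fusiform_R	1.30	0.35	1.34	0.41	-	-	1.27	0.40	1.05	0.33	0.003	3.08
Paracentral_Lobule_L-Paracentral_Lobule_R	1.47	0.39	1.56	0.32	-	-	1.42	0.47	0.99	0.57	<0.001	4.16
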