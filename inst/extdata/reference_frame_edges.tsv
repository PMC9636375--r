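group	label_i	label_j
SWU	Frontal_Sup_L	Frontal_Sup_R
SWU	Frontal_Sup_R	Frontal_Mid_R
SWU	Frontal_Sup_R	Supp_Motor_Area_R
SWU	Supp_Motor_Area_L	Supp_Motor_Area_R
SWU	Frontal_Sup_Medial_L	Frontal_Sup_Medial_R
SWU	Frontal_Mid_Orb_L	Frontal_Mid_Orb_R
SWU	Rolandic_Oper_L	Insula_L
SWU	Insula_L	Insula_R
SWU	Cingulum_Ant_L	Cingulum_Ant_R
SWU	Cingulum_Mid_L	Cingulum_Mid_R
SWU	Cingulum_Post_L	Cingulum_Post_R
SWU	Calcarine_L	Calcarine_R
SWU	Calcarine_L	Cuneus_L
SWU	Calcarine_L	Cuneus_R
SWU	Calcarine_R	Cuneus_R
SWU	Cuneus_L	Cuneus_R
SWU	Calcarine_L	Lingual_L
SWU	Calcarine_R	Lingual_L
SWU	Calcarine_R	Lingual_R
SWU	Lingual_L	Lingual_R
SWU	Cuneus_L	Occipital_Sup_L
SWU	Cuneus_L	Occipital_Sup_R
SWU	Cuneus_R	Occipital_Sup_R
SWU	Occipital_Sup_L	Occipital_Sup_R
SWU	Occipital_Sup_L	Occipital_Mid_L
SWU	Occipital_Sup_L	Occipital_Mid_R
SWU	Occipital_Sup_R	Occipital_Mid_R
SWU	Occipital_Mid_L	Occipital_Mid_R
SWU	Lingual_L	Fusiform_L
SWU	Lingual_R	Fusiform_R
SWU	Fusiform_L	Fusiform_R
SWU	Precentral_R	Postcentral_R
SWU	Postcentral_L	Postcentral_R
SWU	Precuneus_L	Precuneus_R
SWU	Paracentral_Lobule_L	Paracentral_Lobule_R
SWU	Caudate_L	Caudate_R
SWU	Putamen_L	Putamen_R
SWU	Thalamus_L	Thalamus_R
SWU	Temporal_Sup_L	Temporal_Mid_L
SWU	Temporal_Mid_L	Temporal_Mid_R
SWU	Temporal_Mid_R	Temporal_Inf_R
FCP	Precentral_L	Precentral_R
FCP	Frontal_Sup_L	Frontal_Sup_R
FCP	Frontal_Sup_R	Frontal_Mid_R
FCP	Frontal_Mid_L	Frontal_Mid_R
FCP	Rolandic_Oper_L	Rolandic_Oper_R
FCP	Supp_Motor_Area_L	Supp_Motor_Area_R
FCP	Frontal_Sup_Medial_L	Frontal_Sup_Medial_R
FCP	Frontal_Mid_Orb_L	Frontal_Mid_Orb_R
FCP	Insula_L	Insula_R
FCP	Cingulum_Mid_L	Cingulum_Mid_R
FCP	Hippocampus_L	Hippocampus_R
FCP	Calcarine_L	Calcarine_R
FCP	Calcarine_R	Cuneus_R
FCP	Cuneus_L	Cuneus_R
FCP	Calcarine_L	Lingual_L
FCP	Calcarine_R	Lingual_L
FCP	Calcarine_R	Lingual_R
FCP	Lingual_L	Lingual_R
FCP	Cuneus_L	Occipital_Sup_L
FCP	Cuneus_R	Occipital_Sup_R
FCP	Occipital_Sup_L	Occipital_Sup_R
FCP	Occipital_Sup_L	Occipital_Mid_L
FCP	Occipital_Sup_R	Occipital_Mid_R
FCP	Lingual_L	Fusiform_L
FCP	Lingual_L	Fusiform_R
FCP	Lingual_R	Fusiform_R
FCP	Fusiform_L	Fusiform_R
FCP	Precentral_L	Postcentral_L
FCP	Precentral_R	Postcentral_L
FCP	Precentral_R	Postcentral_R
FCP	Postcentral_L	Postcentral_R
FCP	Parietal_Sup_L	Parietal_Sup_R
FCP	Precuneus_L	Precuneus_R
FCP	Paracentral_Lobule_L	Paracentral_Lobule_R
FCP	Caudate_L	Caudate_R
FCP	Putamen_L	Putamen_R
FCP	Thalamus_L	Thalamus_R
FCP	Temporal_Mid_L	Temporal_Mid_R
FCP	Fusiform_R	Temporal_Inf_R
FCP	Temporal_Mid_R	Temporal_Inf_R
FCP	Temporal_Inf_L	Temporal_Inf_R
C-SCH	Precentral_L	Precentral_R
C-SCH	Frontal_Sup_L	Frontal_Sup_R
C-SCH	Precentral_L	Frontal_Mid_L
C-SCH	Frontal_Sup_L	Frontal_Mid_L
C-SCH	Precentral_R	Frontal_Mid_R
C-SCH	Frontal_Sup_R	Frontal_Mid_R
C-SCH	Frontal_Mid_L	Frontal_Mid_R
C-SCH	Frontal_Inf_Orb_L	Frontal_Inf_Orb_R
C-SCH	Frontal_Sup_L	Supp_Motor_Area_L
C-SCH	Frontal_Sup_L	Supp_Motor_Area_R
C-SCH	Supp_Motor_Area_L	Supp_Motor_Area_R
C-SCH	Frontal_Sup_L	Frontal_Sup_Medial_L
C-SCH	Frontal_Mid_L	Frontal_Sup_Medial_L
C-SCH	Frontal_Sup_L	Frontal_Sup_Medial_R
C-SCH	Frontal_Sup_R	Frontal_Sup_Medial_R
C-SCH	Frontal_Mid_L	Frontal_Sup_Medial_R
C-SCH	Frontal_Sup_Medial_L	Frontal_Sup_Medial_R
C-SCH	Frontal_Mid_Orb_L	Frontal_Mid_Orb_R
C-SCH	Rolandic_Oper_L	Insula_L
C-SCH	Rolandic_Oper_R	Insula_R
C-SCH	Insula_L	Insula_R
C-SCH	Cingulum_Ant_L	Cingulum_Ant_R
C-SCH	Cingulum_Mid_L	Cingulum_Mid_R
C-SCH	Cingulum_Post_L	Cingulum_Post_R
C-SCH	Hippocampus_L	Hippocampus_R
C-SCH	Calcarine_L	Calcarine_R
C-SCH	Cuneus_L	Cuneus_R
C-SCH	Lingual_L	Lingual_R
C-SCH	Cuneus_R	Occipital_Sup_R
C-SCH	ParaHippocampal_L	Fusiform_L
C-SCH	Lingual_L	Fusiform_L
C-SCH	Lingual_R	Fusiform_R
C-SCH	Fusiform_L	Fusiform_R
C-SCH	Precentral_L	Postcentral_L
C-SCH	Precentral_R	Postcentral_R
C-SCH	Parietal_Sup_L	Parietal_Sup_R
C-SCH	Precuneus_L	Precuneus_R
C-SCH	Paracentral_Lobule_L	Paracentral_Lobule_R
C-SCH	Caudate_L	Caudate_R
C-SCH	Putamen_L	Putamen_R
C-SCH	Thalamus_L	Thalamus_R
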