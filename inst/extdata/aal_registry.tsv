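region	hemisphere	block	cerebellum
Precentral_L	L	frontal	FALSE
Precentral_R	R	frontal	FALSE
Frontal_Sup_L	L	frontal	FALSE
Frontal_Sup_R	R	frontal	FALSE
Frontal_Sup_Orb_L	L	frontal	FALSE
Frontal_Sup_Orb_R	R	frontal	FALSE
Frontal_Mid_L	L	frontal	FALSE
Frontal_Mid_R	R	frontal	FALSE
Frontal_Mid_Orb_L	L	frontal	FALSE
Frontal_Mid_Orb_R	R	frontal	FALSE
Frontal_Inf_Oper_L	L	frontal	FALSE
Frontal_Inf_Oper_R	R	frontal	FALSE
Frontal_Inf_Tri_L	L	frontal	FALSE
Frontal_Inf_Tri_R	R	frontal	FALSE
Frontal_Inf_Orb_L	L	frontal	FALSE
Frontal_Inf_Orb_R	R	frontal	FALSE
Rolandic_Oper_L	L	frontal	FALSE
Rolandic_Oper_R	R	frontal	FALSE
Supp_Motor_Area_L	L	frontal	FALSE
Supp_Motor_Area_R	R	frontal	FALSE
Olfactory_L	L	frontal	FALSE
Olfactory_R	R	frontal	FALSE
Frontal_Sup_Medial_L	L	frontal	FALSE
Frontal_Sup_Medial_R	R	frontal	FALSE
Frontal_Med_Orb_L	L	frontal	FALSE
Frontal_Med_Orb_R	R	frontal	FALSE
Rectus_L	L	frontal	FALSE
Rectus_R	R	frontal	FALSE
Insula_L	L	subcortical	FALSE
Insula_R	R	subcortical	FALSE
Cingulum_Ant_L	L	subcortical	FALSE
Cingulum_Ant_R	R	subcortical	FALSE
Cingulum_Mid_L	L	subcortical	FALSE
Cingulum_Mid_R	R	subcortical	FALSE
Cingulum_Post_L	L	subcortical	FALSE
Cingulum_Post_R	R	subcortical	FALSE
Hippocampus_L	L	subcortical	FALSE
Hippocampus_R	R	subcortical	FALSE
ParaHippocampal_L	L	subcortical	FALSE
ParaHippocampal_R	R	subcortical	FALSE
Amygdala_L	L	subcortical	FALSE
Amygdala_R	R	subcortical	FALSE
Calcarine_L	L	parieto-occipital	FALSE
Calcarine_R	R	parieto-occipital	FALSE
Cuneus_L	L	parieto-occipital	FALSE
Cuneus_R	R	parieto-occipital	FALSE
Lingual_L	L	parieto-occipital	FALSE
Lingual_R	R	parieto-occipital	FALSE
Occipital_Sup_L	L	parieto-occipital	FALSE
Occipital_Sup_R	R	parieto-occipital	FALSE
Occipital_Mid_L	L	parieto-occipital	FALSE
Occipital_Mid_R	R	parieto-occipital	FALSE
Occipital_Inf_L	L	parieto-occipital	FALSE
Occipital_Inf_R	R	parieto-occipital	FALSE
Fusiform_L	L	temporal-L	FALSE
Fusiform_R	R	temporal-R	FALSE
Postcentral_L	L	parieto-occipital	FALSE
Postcentral_R	R	parieto-occipital	FALSE
Parietal_Sup_L	L	parieto-occipital	FALSE
Parietal_Sup_R	R	parieto-occipital	FALSE
Parietal_Inf_L	L	parieto-occipital	FALSE
Parietal_Inf_R	R	parieto-occipital	FALSE
SupraMarginal_L	L	parieto-occipital	FALSE
SupraMarginal_R	R	parieto-occipital	FALSE
Angular_L	L	parieto-occipital	FALSE
Angular_R	R	parieto-occipital	FALSE
Precuneus_L	L	parieto-occipital	FALSE
Precuneus_R	R	parieto-occipital	FALSE
Paracentral_Lobule_L	L	frontal	FALSE
Paracentral_Lobule_R	R	frontal	FALSE
Caudate_L	L	subcortical	FALSE
Caudate_R	R	subcortical	FALSE
Putamen_L	L	subcortical	FALSE
Putamen_R	R	subcortical	FALSE
Pallidum_L	L	subcortical	FALSE
Pallidum_R	R	subcortical	FALSE
Thalamus_L	L	subcortical	FALSE
Thalamus_R	R	subcortical	FALSE
Heschl_L	L	temporal-L	FALSE
Heschl_R	R	temporal-R	FALSE
Temporal_Sup_L	L	temporal-L	FALSE
Temporal_Sup_R	R	temporal-R	FALSE
Temporal_Pole_Sup_L	L	temporal-L	FALSE
Temporal_Pole_Sup_R	R	temporal-R	FALSE
Temporal_Mid_L	L	temporal-L	FALSE
Temporal_Mid_R	R	temporal-R	FALSE
Temporal_Pole_Mid_L	L	temporal-L	FALSE
Temporal_Pole_Mid_R	R	temporal-R	FALSE
Temporal_Inf_L	L	temporal-L	FALSE
Temporal_Inf_R	R	temporal-R	FALSE
Cerebelum_Crus1_L	L	cerebellar	TRUE
Cerebelum_Crus1_R	R	cerebellar	TRUE
Cerebelum_Crus2_L	L	cerebellar	TRUE
Cerebelum_Crus2_R	R	cerebellar	TRUE
Cerebelum_3_L	L	cerebellar	TRUE
Cerebelum_3_R	R	cerebellar	TRUE
Cerebelum_4_5_L	L	cerebellar	TRUE
Cerebelum_4_5_R	R	cerebellar	TRUE
Cerebelum_6_L	L	cerebellar	TRUE
Cerebelum_6_R	R	cerebellar	TRUE
Cerebelum_7b_L	L	cerebellar	TRUE
Cerebelum_7b_R	R	cerebellar	TRUE
Cerebelum_8_L	L	cerebellar	TRUE
Cerebelum_8_R	R	cerebellar	TRUE
Cerebelum_9_L	L	cerebellar	TRUE
Cerebelum_9_R	R	cerebellar	TRUE
Cerebelum_10_L	L	cerebellar	TRUE
Cerebelum_10_R	R	cerebellar	TRUE
Vermis_1_2	midline	cerebellar	TRUE
Vermis_3	midline	cerebellar	TRUE
Vermis_4_5	midline	cerebellar	TRUE
Vermis_6	midline	cerebellar	TRUE
Vermis_7	midline	cerebellar	TRUE
Vermis_8	midline	cerebellar	TRUE
Vermis_9	midline	cerebellar	TRUE
Vermis_10	midline	cerebellar	TRUE
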