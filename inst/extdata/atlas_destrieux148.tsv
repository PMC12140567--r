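region	hemisphere	lobe
lh-G_and_S_frontomargin	lh	frontal
lh-G_and_S_occipital_inf	lh	occipital
lh-G_and_S_paracentral	lh	frontal
lh-G_and_S_subcentral	lh	frontal
lh-G_and_S_transv_frontopol	lh	frontal
lh-G_and_S_cingul-Ant	lh	cingulate
lh-G_and_S_cingul-Mid-Ant	lh	cingulate
lh-G_and_S_cingul-Mid-Post	lh	cingulate
lh-G_cingul-Post-dorsal	lh	cingulate
lh-G_cingul-Post-ventral	lh	cingulate
lh-G_cuneus	lh	occipital
lh-G_front_inf-Opercular	lh	frontal
lh-G_front_inf-Orbital	lh	frontal
lh-G_front_inf-Triangul	lh	frontal
lh-G_front_middle	lh	frontal
lh-G_front_sup	lh	frontal
lh-G_Ins_lg_and_S_cent_ins	lh	frontal
lh-G_insular_short	lh	insula
lh-G_occipital_middle	lh	occipital
lh-G_occipital_sup	lh	occipital
lh-G_oc-temp_lat-fusifor	lh	temporal
lh-G_oc-temp_med-Lingual	lh	temporal
lh-G_oc-temp_med-Parahip	lh	temporal
lh-G_orbital	lh	frontal
lh-G_pariet_inf-Angular	lh	parietal
lh-G_pariet_inf-Supramar	lh	parietal
lh-G_parietal_sup	lh	parietal
lh-G_postcentral	lh	parietal
lh-G_precentral	lh	frontal
lh-G_precuneus	lh	occipital
lh-G_rectus	lh	frontal
lh-G_subcallosal	lh	cingulate
lh-G_temp_sup-G_T_transv	lh	temporal
lh-G_temp_sup-Lateral	lh	temporal
lh-G_temp_sup-Plan_polar	lh	temporal
lh-G_temp_sup-Plan_tempo	lh	temporal
lh-G_temporal_inf	lh	temporal
lh-G_temporal_middle	lh	temporal
lh-Lat_Fis-ant-Horizont	lh	frontal
lh-Lat_Fis-ant-Vertical	lh	frontal
lh-Lat_Fis-post	lh	frontal
lh-Pole_occipital	lh	occipital
lh-Pole_temporal	lh	temporal
lh-S_calcarine	lh	occipital
lh-S_central	lh	frontal
lh-S_cingul-Marginalis	lh	cingulate
lh-S_circular_insula_ant	lh	insula
lh-S_circular_insula_inf	lh	insula
lh-S_circular_insula_sup	lh	insula
lh-S_collat_transv_ant	lh	frontal
lh-S_collat_transv_post	lh	frontal
lh-S_front_inf	lh	frontal
lh-S_front_middle	lh	frontal
lh-S_front_sup	lh	frontal
lh-S_interm_prim-Jensen	lh	parietal
lh-S_intrapariet_and_P_trans	lh	parietal
lh-S_oc_middle_and_Lunatus	lh	occipital
lh-S_oc_sup_and_transversal	lh	frontal
lh-S_occipital_ant	lh	occipital
lh-S_oc-temp_lat	lh	temporal
lh-S_oc-temp_med_and_Lingual	lh	temporal
lh-S_orbital_lateral	lh	frontal
lh-S_orbital_med-olfact	lh	frontal
lh-S_orbital-H_Shaped	lh	frontal
lh-S_parieto_occipital	lh	occipital
lh-S_pericallosal	lh	cingulate
lh-S_postcentral	lh	parietal
lh-S_precentral-inf-part	lh	frontal
lh-S_precentral-sup-part	lh	frontal
lh-S_suborbital	lh	cingulate
lh-S_subparietal	lh	parietal
lh-S_temporal_inf	lh	temporal
lh-S_temporal_sup	lh	temporal
lh-S_temporal_transverse	lh	temporal
rh-G_and_S_frontomargin	rh	frontal
rh-G_and_S_occipital_inf	rh	occipital
rh-G_and_S_paracentral	rh	frontal
rh-G_and_S_subcentral	rh	frontal
rh-G_and_S_transv_frontopol	rh	frontal
rh-G_and_S_cingul-Ant	rh	cingulate
rh-G_and_S_cingul-Mid-Ant	rh	cingulate
rh-G_and_S_cingul-Mid-Post	rh	cingulate
rh-G_cingul-Post-dorsal	rh	cingulate
rh-G_cingul-Post-ventral	rh	cingulate
rh-G_cuneus	rh	occipital
rh-G_front_inf-Opercular	rh	frontal
rh-G_front_inf-Orbital	rh	frontal
rh-G_front_inf-Triangul	rh	frontal
rh-G_front_middle	rh	frontal
rh-G_front_sup	rh	frontal
rh-G_Ins_lg_and_S_cent_ins	rh	frontal
rh-G_insular_short	rh	insula
rh-G_occipital_middle	rh	occipital
rh-G_occipital_sup	rh	occipital
rh-G_oc-temp_lat-fusifor	rh	temporal
rh-G_oc-temp_med-Lingual	rh	temporal
rh-G_oc-temp_med-Parahip	rh	temporal
rh-G_orbital	rh	frontal
rh-G_pariet_inf-Angular	rh	parietal
rh-G_pariet_inf-Supramar	rh	parietal
rh-G_parietal_sup	rh	parietal
rh-G_postcentral	rh	parietal
rh-G_precentral	rh	frontal
rh-G_precuneus	rh	occipital
rh-G_rectus	rh	frontal
rh-G_subcallosal	rh	cingulate
rh-G_temp_sup-G_T_transv	rh	temporal
rh-G_temp_sup-Lateral	rh	temporal
rh-G_temp_sup-Plan_polar	rh	temporal
rh-G_temp_sup-Plan_tempo	rh	temporal
rh-G_temporal_inf	rh	temporal
rh-G_temporal_middle	rh	temporal
rh-Lat_Fis-ant-Horizont	rh	frontal
rh-Lat_Fis-ant-Vertical	rh	frontal
rh-Lat_Fis-post	rh	frontal
rh-Pole_occipital	rh	occipital
rh-Pole_temporal	rh	temporal
rh-S_calcarine	rh	occipital
rh-S_central	rh	frontal
rh-S_cingul-Marginalis	rh	cingulate
rh-S_circular_insula_ant	rh	insula
rh-S_circular_insula_inf	rh	insula
rh-S_circular_insula_sup	rh	insula
rh-S_collat_transv_ant	rh	frontal
rh-S_collat_transv_post	rh	frontal
rh-S_front_inf	rh	frontal
rh-S_front_middle	rh	frontal
rh-S_front_sup	rh	frontal
rh-S_interm_prim-Jensen	rh	parietal
rh-S_intrapariet_and_P_trans	rh	parietal
rh-S_oc_middle_and_Lunatus	rh	occipital
rh-S_oc_sup_and_transversal	rh	frontal
rh-S_occipital_ant	rh	occipital
rh-S_oc-temp_lat	rh	temporal
rh-S_oc-temp_med_and_Lingual	rh	temporal
rh-S_orbital_lateral	rh	frontal
rh-S_orbital_med-olfact	rh	frontal
rh-S_orbital-H_Shaped	rh	frontal
rh-S_parieto_occipital	rh	occipital
rh-S_pericallosal	rh	cingulate
rh-S_postcentral	rh	parietal
rh-S_precentral-inf-part	rh	frontal
rh-S_precentral-sup-part	rh	frontal
rh-S_suborbital	rh	cingulate
rh-S_subparietal	rh	parietal
rh-S_temporal_inf	rh	temporal
rh-S_temporal_sup	rh	temporal
rh-S_temporal_transverse	rh	temporal
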