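name,hemisphere,homologue,x_cm,y_cm,z_cm
Precentral_L,L,Precentral_R,-3.18,-0.28,3.19
Precentral_R,R,Precentral_L,3.22,-0.09,3.43
Frontal_Sup_L,L,Frontal_Sup_R,-3.07,-5.7,-2.21
Frontal_Sup_R,R,Frontal_Sup_L,2.82,-5.65,-2.48
Frontal_Sup_Orb_L,L,Frontal_Sup_Orb_R,-4.17,1.42,3.14
Frontal_Sup_Orb_R,R,Frontal_Sup_Orb_L,4.15,1.62,3.07
Frontal_Mid_L,L,Frontal_Mid_R,-4.02,6.26,-1.76
Frontal_Mid_R,R,Frontal_Mid_L,4.36,6.23,-1.61
Frontal_Mid_Orb_L,L,Frontal_Mid_Orb_R,-5.72,6.21,4.05
Frontal_Mid_Orb_R,R,Frontal_Mid_Orb_L,5.79,6.25,3.8
Frontal_Inf_Oper_L,L,Frontal_Inf_Oper_R,-5.31,-4.75,6.21
Frontal_Inf_Oper_R,R,Frontal_Inf_Oper_L,5.37,-4.98,6.19
Frontal_Inf_Tri_L,L,Frontal_Inf_Tri_R,-3.76,-2.92,-2.13
Frontal_Inf_Tri_R,R,Frontal_Inf_Tri_L,3.82,-3.01,-2.06
Frontal_Inf_Orb_L,L,Frontal_Inf_Orb_R,-5.31,-2.93,-0.52
Frontal_Inf_Orb_R,R,Frontal_Inf_Orb_L,5.32,-2.85,-0.55
Rolandic_Oper_L,L,Rolandic_Oper_R,-3.31,3.89,-2.92
Rolandic_Oper_R,R,Rolandic_Oper_L,3.13,4.14,-3.09
Supp_Motor_Area_L,L,Supp_Motor_Area_R,-2.99,-1.04,0.76
Supp_Motor_Area_R,R,Supp_Motor_Area_L,2.98,-0.78,0.73
Olfactory_L,L,Olfactory_R,-4.2,1.82,2.31
Olfactory_R,R,Olfactory_L,4.18,1.7,2.45
Frontal_Sup_Medial_L,L,Frontal_Sup_Medial_R,-3.06,-0.15,0.79
Frontal_Sup_Medial_R,R,Frontal_Sup_Medial_L,3.12,-0.12,0.86
Frontal_Med_Orb_L,L,Frontal_Med_Orb_R,-4.13,-2.89,0.54
Frontal_Med_Orb_R,R,Frontal_Med_Orb_L,4.26,-2.91,0.4
Rectus_L,L,Rectus_R,-2.35,-2.67,4.73
Rectus_R,R,Rectus_L,2.27,-2.64,4.87
Insula_L,L,Insula_R,-4.8,-1.1,-3.79
Insula_R,R,Insula_L,4.82,-1.19,-3.76
Cingulum_Ant_L,L,Cingulum_Ant_R,-4.55,7.1,-2.24
Cingulum_Ant_R,R,Cingulum_Ant_L,4.8,6.95,-2.14
Cingulum_Mid_L,L,Cingulum_Mid_R,-5.4,-4.54,-2.39
Cingulum_Mid_R,R,Cingulum_Mid_L,5.3,-4.75,-2.39
Cingulum_Post_L,L,Cingulum_Post_R,-5.77,6.39,1.28
Cingulum_Post_R,R,Cingulum_Post_L,5.79,6.38,1.2
Hippocampus_L,L,Hippocampus_R,-2.98,-1.48,-1.4
Hippocampus_R,R,Hippocampus_L,3,-1.67,-1.5
ParaHippocampal_L,L,ParaHippocampal_R,-2.71,-4.2,5.41
ParaHippocampal_R,R,ParaHippocampal_L,2.55,-4.15,5.4
Amygdala_L,L,Amygdala_R,-5.46,-0.79,6.17
Amygdala_R,R,Amygdala_L,5.51,-0.88,6.38
Calcarine_L,L,Calcarine_R,-3.51,6.84,1.78
Calcarine_R,R,Calcarine_L,3.58,6.53,1.81
Cuneus_L,L,Cuneus_R,-3.24,-4.67,-0.85
Cuneus_R,R,Cuneus_L,3.45,-4.56,-0.97
Lingual_L,L,Lingual_R,-4.58,-3.69,-1.55
Lingual_R,R,Lingual_L,4.67,-3.43,-1.52
Occipital_Sup_L,L,Occipital_Sup_R,-5.06,3.85,-0.91
Occipital_Sup_R,R,Occipital_Sup_L,5.37,3.73,-0.87
Occipital_Mid_L,L,Occipital_Mid_R,-4.74,-4.47,-3.41
Occipital_Mid_R,R,Occipital_Mid_L,4.6,-4.47,-3.35
Occipital_Inf_L,L,Occipital_Inf_R,-4.94,-0.74,5.84
Occipital_Inf_R,R,Occipital_Inf_L,5.03,-0.62,5.65
Fusiform_L,L,Fusiform_R,-4.35,4.15,3.63
Fusiform_R,R,Fusiform_L,4.48,4.13,3.69
Postcentral_L,L,Postcentral_R,-1.99,3.71,1.2
Postcentral_R,R,Postcentral_L,2.08,3.75,1.3
Parietal_Sup_L,L,Parietal_Sup_R,-2.59,3.74,0.76
Parietal_Sup_R,R,Parietal_Sup_L,2.4,3.68,1.01
Parietal_Inf_L,L,Parietal_Inf_R,-2.3,-1.41,6.66
Parietal_Inf_R,R,Parietal_Inf_L,2.3,-1.29,6.63
SupraMarginal_L,L,SupraMarginal_R,-2.52,0.56,-0.87
SupraMarginal_R,R,SupraMarginal_L,2.53,0.56,-0.91
Angular_L,L,Angular_R,-4.42,3.33,3.39
Angular_R,R,Angular_L,4.32,3.27,3.64
Precuneus_L,L,Precuneus_R,-3.16,1.67,1.64
Precuneus_R,R,Precuneus_L,3.27,1.63,1.62
Paracentral_Lobule_L,L,Paracentral_Lobule_R,-2.65,2.39,0.76
Paracentral_Lobule_R,R,Paracentral_Lobule_L,2.62,2.55,0.9
Caudate_L,L,Caudate_R,-2.22,-2.51,4.57
Caudate_R,R,Caudate_L,2.27,-2.54,4.62
Putamen_L,L,Putamen_R,-5.4,3.52,2.37
Putamen_R,R,Putamen_L,5.57,3.44,2.45
Pallidum_L,L,Pallidum_R,-4.73,-3.48,1.97
Pallidum_R,R,Pallidum_L,4.59,-3.31,2.12
Thalamus_L,L,Thalamus_R,-2.09,-1.11,0.77
Thalamus_R,R,Thalamus_L,2.37,-1.25,0.63
Heschl_L,L,Heschl_R,-4.91,3.81,-0.94
Heschl_R,R,Heschl_L,4.8,3.72,-1.01
Temporal_Sup_L,L,Temporal_Sup_R,-2.88,-4.88,-4
Temporal_Sup_R,R,Temporal_Sup_L,2.87,-4.93,-3.84
Temporal_Pole_Sup_L,L,Temporal_Pole_Sup_R,-5.93,2.58,-0.14
Temporal_Pole_Sup_R,R,Temporal_Pole_Sup_L,5.95,2.56,-0.37
Temporal_Mid_L,L,Temporal_Mid_R,-2.88,1.77,-1.37
Temporal_Mid_R,R,Temporal_Mid_L,2.68,1.54,-1.41
Temporal_Pole_Mid_L,L,Temporal_Pole_Mid_R,-2.99,-5.72,1.55
Temporal_Pole_Mid_R,R,Temporal_Pole_Mid_L,3.04,-5.59,1.55
Temporal_Inf_L,L,Temporal_Inf_R,-3.36,4.81,-0.06
Temporal_Inf_R,R,Temporal_Inf_L,3.35,4.92,-0.25
Cerebelum_Crus1_L,L,Cerebelum_Crus1_R,-4.83,4.18,5.74
Cerebelum_Crus1_R,R,Cerebelum_Crus1_L,4.83,4.27,5.83
Cerebelum_Crus2_L,L,Cerebelum_Crus2_R,-2.72,3.43,5.29
Cerebelum_Crus2_R,R,Cerebelum_Crus2_L,2.5,3.69,5.31
Cerebelum_3_R,R,,5.62,2.68,-1.98
Cerebelum_4_5_L,L,Cerebelum_4_5_R,-4,-1.11,4.36
Cerebelum_4_5_R,R,Cerebelum_4_5_L,4.21,-1.37,4.07
Cerebelum_6_L,L,Cerebelum_6_R,-2.74,6.01,-2.78
Cerebelum_6_R,R,Cerebelum_6_L,2.75,5.96,-2.65
Cerebelum_7b_L,L,Cerebelum_7b_R,-3.88,-4.96,-3.63
Cerebelum_7b_R,R,Cerebelum_7b_L,3.86,-5.04,-3.44
Cerebelum_8_L,L,Cerebelum_8_R,-5.17,-7.24,1.78
Cerebelum_8_R,R,Cerebelum_8_L,5.17,-7.34,1.59
Cerebelum_9_L,L,Cerebelum_9_R,-2.5,2.92,2.31
Cerebelum_9_R,R,Cerebelum_9_L,2.89,2.68,2.35
Cerebelum_10_L,L,Cerebelum_10_R,-3.26,1.69,0.33
Cerebelum_10_R,R,Cerebelum_10_L,3.2,1.26,0.5
Vermis_1_2,M,,0.38,-5.44,-0.91
Vermis_3,M,,-0.09,-6.14,-2.56
Vermis_4_5,M,,0.19,-4.95,-3.6
Vermis_6,M,,-0.07,-5.71,-2.82
Vermis_7,M,,0.14,-4.47,-3.29
Vermis_8,M,,0.13,-4.41,-2.54
Vermis_9,M,,-0.21,-4.12,-3.82
Vermis_10,M,,-0.16,-6.1,-2.05
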