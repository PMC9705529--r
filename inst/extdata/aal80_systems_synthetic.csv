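node_id,label,system
0,Precentral_L,SMN
1,Precentral_R,SMN
2,Postcentral_L,SMN
3,Postcentral_R,SMN
4,Paracentral_Lobule_L,SMN
5,Paracentral_Lobule_R,SMN
6,Supp_Motor_Area_L,SMN
7,Supp_Motor_Area_R,SMN
8,Rolandic_Oper_L,SMN
9,Rolandic_Oper_R,SMN
10,Frontal_Sup_Medial_L,DMN
11,Frontal_Sup_Medial_R,DMN
12,Frontal_Med_Orb_L,DMN
13,Frontal_Med_Orb_R,DMN
14,Cingulum_Ant_L,DMN
15,Cingulum_Ant_R,DMN
16,Cingulum_Post_L,DMN
17,Cingulum_Post_R,DMN
18,Precuneus_L,DMN
19,Precuneus_R,DMN
20,Angular_L,DMN
21,Angular_R,DMN
22,Temporal_Mid_L,DMN
23,Temporal_Mid_R,DMN
24,Calcarine_L,VN
25,Calcarine_R,VN
26,Cuneus_L,VN
27,Cuneus_R,VN
28,Lingual_L,VN
29,Lingual_R,VN
30,Occipital_Sup_L,VN
31,Occipital_Sup_R,VN
32,Occipital_Mid_L,VN
33,Occipital_Mid_R,VN
34,Occipital_Inf_L,VN
35,Occipital_Inf_R,VN
36,Fusiform_L,VN
37,Fusiform_R,VN
38,Frontal_Sup_L,ATN
39,Frontal_Sup_R,ATN
40,Frontal_Mid_L,ATN
41,Frontal_Mid_R,ATN
42,Parietal_Sup_L,ATN
43,Parietal_Sup_R,ATN
44,Parietal_Inf_L,ATN
45,Parietal_Inf_R,ATN
46,Frontal_Inf_Oper_L,TPN
47,Frontal_Inf_Oper_R,TPN
48,Frontal_Inf_Tri_L,TPN
49,Frontal_Inf_Tri_R,TPN
50,Supramarginal_L,TPN
51,Supramarginal_R,TPN
52,Insula_L,TPN
53,Insula_R,TPN
54,Temporal_Sup_L,Others
55,Temporal_Sup_R,Others
56,Temporal_Pole_Sup_L,Others
57,Temporal_Pole_Sup_R,Others
58,Temporal_Inf_L,Others
59,Temporal_Inf_R,Others
60,Temporal_Pole_Mid_L,Others
61,Temporal_Pole_Mid_R,Others
62,Heschl_L,Others
63,Heschl_R,Others
64,Olfactory_L,Others
65,Olfactory_R,Others
66,Rectus_L,Others
67,Rectus_R,Others
68,Frontal_Sup_Orb_L,Others
69,Frontal_Sup_Orb_R,Others
70,Frontal_Mid_Orb_L,Others
71,Frontal_Mid_Orb_R,Others
72,Frontal_Inf_Orb_L,Others
73,Frontal_Inf_Orb_R,Others
74,Cingulum_Mid_L,Others
75,Cingulum_Mid_R,Others
76,ParaHippocampal_L,Others
77,ParaHippocampal_R,Others
78,Hippocampus_L,Others
79,Hippocampus_R,Others
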