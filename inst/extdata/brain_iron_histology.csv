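region,label_ids,age_group,transferrin_ng_ug,n_transferrin,ferritin_ng_ug,n_ferritin,iron_mg_g,n_iron,transferrin_source,ferritin_source,iron_source
Frontal CTX,1003;1012;1014;1019;1020;1027;1028;1032,younger,3.88,9,45.34,9,1.21,9,elisa_cohort,slotblot_cohort,elisa_cohort
Frontal CTX,1003;1012;1014;1019;1020;1027;1028;1032,older,4.09,11,89.77,11,1.59,11,elisa_cohort,slotblot_cohort,elisa_cohort
Caudate,11,younger,3.21,8,60.92,7,1.79,8,elisa_cohort,slotblot_cohort,elisa_cohort
Caudate,11,older,4.44,8,135.12,8,3.34,8,elisa_cohort,slotblot_cohort,elisa_cohort
Putamen,12,younger,3.49,8,58.63,7,2.59,8,elisa_cohort,slotblot_cohort,elisa_cohort
Putamen,12,older,4.47,8,124.12,8,4.62,8,elisa_cohort,slotblot_cohort,elisa_cohort
Substantia nigra (midbrain),173,younger,2.45,8,54.96,7,2.92,8,elisa_cohort,slotblot_cohort,elisa_cohort
Substantia nigra (midbrain),173,older,3.42,8,135.12,8,5.70,8,elisa_cohort,slotblot_cohort,elisa_cohort
Globus pallidus,13,younger,4.82,8,28.40,7,7.39,8,elisa_cohort,slotblot_cohort,elisa_cohort
Globus pallidus,13,older,5.10,8,215.27,8,4.07,8,elisa_cohort,slotblot_cohort,elisa_cohort
Temporal CTX (gray superior temporal gyrus),1001;1006;1007;1009;1015;1016;1030;1033;1034,younger,1.84,9,25.65,9,0.45,9,blot_cohort,blot_cohort,blot_cohort
Temporal CTX (gray superior temporal gyrus),1001;1006;1007;1009;1015;1016;1030;1033;1034,older,1.08,11,24.20,11,0.69,11,blot_cohort,blot_cohort,blot_cohort
Temporal WM (white superior temporal gyrus),3001;3006;3007;3009;3015;3016;3034;3030;3033,younger,3.82,9,44.87,9,0.72,9,blot_cohort,blot_cohort,blot_cohort
Temporal WM (white superior temporal gyrus),3001;3006;3007;3009;3015;3016;3034;3030;3033,older,2.52,11,33.50,11,0.74,11,blot_cohort,blot_cohort,blot_cohort
Motor CTX,1017;1022;1024;1031,younger,2.91,9,40.20,9,1.16,9,blot_cohort,blot_cohort,blot_cohort
Motor CTX,1017;1022;1024;1031,older,2.93,11,22.13,11,0.89,11,blot_cohort,blot_cohort,blot_cohort
Motor WM,3024;3017;3022;3031,younger,5.75,9,30.38,9,1.39,9,blot_cohort,blot_cohort,blot_cohort
Motor WM,3024;3017;3022;3031,older,7.34,11,21.51,11,1.25,11,blot_cohort,blot_cohort,blot_cohort
Occipital CTX,1011;1013;1005;1021,younger,1.75,9,9.34,9,0.50,9,blot_cohort,blot_cohort,blot_cohort
Occipital CTX,1011;1013;1005;1021,older,1.67,11,34.27,11,1.16,11,blot_cohort,blot_cohort,blot_cohort
Occipital WM,3011;3013;3005;3021,younger,3.53,9,13.81,9,0.80,9,blot_cohort,blot_cohort,blot_cohort
Occipital WM,3011;3013;3005;3021,older,6.07,11,31.38,11,0.90,11,blot_cohort,blot_cohort,blot_cohort
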