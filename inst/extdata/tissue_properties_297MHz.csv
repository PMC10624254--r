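tissue,is_liquid,permittivity_ratio,permittivity,conductivity_ratio,conductivity,perfusion_ratio,perfusion,density,heat_capacity,thermal_conductivity,metabolic_rate
Adrenal gland,FALSE,1.23,76.60,1.32,0.89,1.72,2505,1027,3513,0.44,5.0
Air,FALSE,1.00,1.00,1.00,0.00,1.00,0,1.2,1004,0.026,0
Air (internal),FALSE,1.00,1.00,1.00,0.00,1.00,0,1.2,1004,0.026,0
Bile,TRUE,1.00,74.97,1.00,1.67,1.00,0,1030,4000,0.55,0
Blood,TRUE,1.00,65.70,1.00,1.32,1.00,10000,1050,3617,0.52,0
Blood vessel wall,FALSE,1.24,60.04,1.36,0.73,1.00,150,1102,3306,0.46,1.0
Bone (Cortical),FALSE,1.84,24.78,2.42,0.20,1.72,17,1908,1313,0.32,0.15
Bone marrow (red),FALSE,1.24,15.07,1.36,0.24,1.72,232,1029,2666,0.28,1.0
Brain (grey matter),FALSE,1.33,79.79,1.51,1.04,2.21,1685,1045,3696,0.55,15.5
Brain (white matter),FALSE,1.33,58.19,1.51,0.62,2.21,468,1041,3583,0.48,4.5
Bronchi,FALSE,1.24,56.28,1.36,0.83,1.72,409,1080,3568,0.47,1.0
Cartilage,FALSE,1.24,58.11,1.36,0.75,1.72,409,1100,3568,0.49,0.54
Cerebellum,FALSE,1.33,79.45,1.51,1.47,1.72,60,1045,3653,0.51,11.4
Cerebrospinal fluid,TRUE,1.00,72.80,1.00,2.22,2.21,1699,1007,4096,0.57,0
Commissura anterior,FALSE,1.33,58.19,1.51,0.62,0.00,0,1041,3583,0.48,4.5
Commissura posterior,FALSE,1.33,58.19,1.51,0.62,2.21,468,1041,3583,0.48,4.5
Connective tissue,FALSE,1.24,59.59,1.36,0.73,1.72,63.9,1142,3432,0.47,0.54
Diaphragm,FALSE,1.20,69.62,1.36,1.05,1.72,170,1090,3421,0.49,0.91
Dura,FALSE,1.33,63.72,1.51,1.21,2.21,838,1174,3364,0.44,1.0
Esophagus,FALSE,1.24,85.34,1.36,1.32,1.72,326,1088,3690,0.53,1.0
Eye (aqueous humor),TRUE,1.00,72.80,1.00,2.22,1.00,0,1003,4178,0.58,0
Eye (cornea),FALSE,1.24,76.27,1.36,1.56,1.00,0,1051,4178,0.54,0
Eye (lens),FALSE,1.24,47.65,1.36,0.48,1.00,0,1076,3133,0.43,0
Eye (retina),FALSE,1.33,79.79,1.51,1.04,1.72,412,1045,3696,0.55,10.0
Eye (sclera),FALSE,1.24,73.16,1.36,1.33,2.21,838,1032,4200,0.58,0.54
Eye (vitreous humor),TRUE,1.00,69.02,1.00,1.52,0.00,0,1005,4047,0.59,0
Fat,FALSE,1.24,14.58,1.36,0.10,1.72,56,911,2348,0.21,0.51
Gallbladder,FALSE,1.00,62.99,1.00,1.12,1.72,52,1071,3716,0.52,1.0
Heart muscle,FALSE,1.20,82.99,1.36,1.23,1.13,1158,1081,3686,0.56,39.0
Hippocampus,FALSE,1.33,79.79,1.51,1.04,2.21,1685,1045,3696,0.55,15.5
Hypophysis,FALSE,1.23,76.89,1.32,1.13,2.21,1952,1053,3687,0.56,5.0
Hypothalamus,FALSE,1.33,79.79,1.51,1.04,2.21,1685,1045,3696,0.55,15.5
Intervertebral Disc,FALSE,1.24,58.65,1.36,1.24,1.72,60,1100,3568,0.49,0.54
Intestine contents,TRUE,1.00,58.24,1.00,0.77,1.00,0,1045,3700,0.54,0
Kidney,FALSE,1.24,87.67,1.36,1.39,1.21,4575,1066,3763,0.53,18.0
Large intestine,FALSE,1.24,80.80,1.36,1.10,1.23,943,1088,3655,0.54,1.0
Larynx,FALSE,1.24,58.11,1.36,0.75,1.72,60,1100,3568,0.47,0.54
Liver,FALSE,1.21,64.93,1.25,0.76,1.20,1034,1079,3540,0.52,9.9
Lung,FALSE,1.24,30.79,1.36,0.48,1.72,689,394,3886,0.39,1.0
Mandible,FALSE,1.84,24.78,2.42,0.20,1.72,17,1908,1313,0.32,0.15
Medulla oblongata,FALSE,1.33,79.45,1.51,1.47,2.21,1232,1046,3630,0.51,11.4
Midbrain,FALSE,1.33,79.45,1.51,1.47,2.21,1232,1046,3630,0.51,11.4
Mucous membrane,FALSE,1.20,69.62,1.36,1.05,1.72,1020,1102,3150,0.33,1.0
Muscle,FALSE,1.20,69.62,1.36,1.05,1.13,41,1090,3421,0.49,0.91
Nerve,FALSE,1.24,45.88,1.36,0.57,1.72,275,1075,3613,0.49,7.0
Ovary,FALSE,1.24,76.25,1.36,1.28,1.72,405,1048,3215,0.52,2.0
Pancreas,FALSE,1.23,76.89,1.32,1.13,1.37,1049,1087,3164,0.51,4.9
Pineal body,FALSE,1.23,76.89,1.32,1.13,2.21,1952,1053,3687,0.56,5.0
Placenta,FALSE,1.00,65.70,1.00,1.32,1.72,2920,1050,3617,0.52,2.0
Pons,FALSE,1.33,79.45,1.51,1.47,2.21,1232,1046,3630,0.51,11.4
Salivary gland,FALSE,1.23,95.99,1.32,0.95,1.72,658,1048,3596,0.53,5.0
SAT (subcutaneous fat),FALSE,1.24,14.58,1.36,0.10,1.72,56,911,2348,0.21,0.51
Skin,FALSE,1.29,64.58,1.47,0.94,1.49,159,1109,3391,0.37,1.65
Skull cortical,FALSE,1.84,24.78,2.42,0.20,1.72,17,1908,1313,0.32,0.15
Small intestine,FALSE,1.24,86.76,1.36,2.50,1.23,1264,1030,3595,0.49,1.0
Spinal cord,FALSE,1.24,45.88,1.36,0.57,1.72,275,1075,3613,0.49,7.0
Spleen,FALSE,1.24,82.68,1.36,1.32,1.27,1972,1089,3596,0.53,5.2
Stomach,FALSE,1.24,85.34,1.36,1.32,1.23,565,1088,3690,0.53,1.0
Tendon\ligament,FALSE,1.24,59.59,1.36,0.73,1.72,50,1142,3432,0.47,0.54
Thalamus,FALSE,1.33,79.79,1.51,1.04,2.21,1510,1045,3696,0.55,15.5
Thymus,FALSE,1.24,66.67,1.36,0.00,1.72,424,1023,3600,0.52,2.0
Thyroid gland,FALSE,1.23,76.89,1.32,1.13,1.72,9659,1050,3609,0.52,7.0
Tongue,FALSE,1.24,73.16,1.36,1.01,1.13,88,1090,3421,0.49,0.91
Tooth,FALSE,1.84,24.78,2.42,0.20,1.00,0,2180,1260,0.59,0
Trachea,FALSE,1.24,56.28,1.36,0.83,1.72,60,1080,3568,0.47,1.0
Uterus,FALSE,1.24,60.04,1.36,0.73,1.72,787,1105,3371,0.53,1.0
Urinary bladder Wall,FALSE,1.24,24.96,1.36,0.43,1.72,134,1086,3581,0.52,1.0
Urine,TRUE,1.00,49.95,1.00,1.75,1.00,0,1024,4178,0.56,0
Vagina,FALSE,1.24,80.80,1.36,1.10,1.72,168,1105,3371,0.53,1.0
Vertebrae,FALSE,1.84,24.78,2.42,0.20,1.72,17,1908,1313,0.32,0.15
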