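tissue,rater,dsc,hausdorff_mm
Gallbladder,1,0.86,0.55
Gallbladder,2,0.82,0.70
Gallbladder,3,0.94,0.28
Urinary bladder,1,0.88,1.66
Urinary bladder,2,0.92,1.01
Urinary bladder,3,0.96,0.57
Kidney left,1,0.96,0.34
Kidney left,2,0.96,0.39
Kidney left,3,0.98,0.18
Lung right,1,0.99,0.12
Lung right,2,0.99,0.15
Lung right,3,0.99,0.08
Liver,1,0.99,0.15
Liver,2,0.99,0.23
Liver,3,0.99,0.05
Heart muscle,1,0.96,0.10
Heart muscle,2,0.99,0.01
Heart muscle,3,0.99,0.01
Spleen,1,0.81,2.09
Spleen,2,0.98,0.27
Spleen,3,0.99,0.02
Uterus,1,0.99,0.04
Uterus,2,0.86,0.35
Uterus,3,0.95,0.14
Vagina,1,0.98,0.04
Vagina,2,0.92,0.15
Vagina,3,0.90,0.19
Humerus right,1,0.98,0.11
Humerus right,2,0.99,0.05
Humerus right,3,0.99,0.01
Tibia right,1,0.98,0.12
Tibia right,2,0.99,0.03
Tibia right,3,0.99,0.04
Femur right,1,0.94,0.35
Femur right,2,0.92,0.49
Femur right,3,0.99,0.01
Fibula right,1,0.96,0.80
Fibula right,2,0.99,0.01
Fibula right,3,0.99,0.01
Ulna right,1,0.97,0.08
Ulna right,2,0.95,0.16
Ulna right,3,0.99,0.02
"Air nose, sinuses",1,0.94,0.13
"Air nose, sinuses",2,0.97,0.06
"Air nose, sinuses",3,0.97,0.06
Vitreous body right,1,0.96,0.18
Vitreous body right,2,0.95,0.25
Vitreous body right,3,0.98,0.11
Radius right,1,0.97,0.16
Radius right,2,0.97,0.16
Radius right,3,0.99,0.01
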