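tissue,measurement,measured,low,high,source,note
Lung right,weight_g,238.5,120,320,Chang2015,
Lung left,weight_g,159.7,120,320,Chang2015,
Brain,weight_g,1084.8,1000,1100,Chang2015,
Brain CSF,volume_cm3,104.5,110,120,Matsuzawa2001,
Heart,weight_g,82.4,50,90,Chang2015,
Kidneys combined,weight_g,79.46,70,110,Chang2015,
Kidney right,length_cm,62.7,40,70,Konus1998,units printed as length (cm) but magnitude consistent with weight (g); both readings conflicting
Kidney left,length_cm,59.3,40,70,Konus1998,units printed as length (cm) but magnitude consistent with weight (g); both readings conflicting
Liver,weight_g,486.2,400,500,Chang2015,
Liver,length_cm,93.3,45,95,Konus1998,
Pancreas,weight_g,23.2,20,35,ICRP89,
Spleen,weight_g,59.8,30,60,Chang2015,
Spleen,length_cm,72.6,40,75,Konus1998,
Stomach,weight_g,42.9,20,48,Chang2015,
Thymus,weight_g,30,25,35,Chang2015,
Ovaries,volume_cm3,2.5,0.6,3.6,Kelsey2013,
Ovaries,weight_g,2.4,0.8,2,ICRP89,
Sternal bone,length_cm,6.1,7.5,7.5,Weaver2014,single reference value; no range given
Radius/humerus,ratio,0.76,0.71,0.78,Pfeil2010,
Tibia/femur,ratio,0.8,0.78,0.84,Pfeil2010,
Humerus/femur,ratio,0.7,0.67,0.75,Pfeil2010,
Radius/tibia,ratio,0.68,0.61,0.70,Pfeil2010,
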