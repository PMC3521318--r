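species,genotype,dd,lai,inclination_deg,height_m
pea,China,300,0.11,20.8,0.175
pea,China,600,0.81,30.2,0.707
pea,China,1240,1.81,40.9,1.271
pea,US13,300,0.13,32.3,0.144
pea,US13,600,0.79,32.9,0.455
pea,US13,1240,2.42,46.6,0.947
pea,Lucy,300,0.06,44.5,0.132
pea,Lucy,600,0.29,43.3,0.327
pea,Lucy,1240,1.29,48.7,0.836
pea,James,300,0.08,38.0,0.138
pea,James,600,0.34,39.3,0.361
pea,James,1240,1.12,45.2,0.813
pea,AOPH10,300,0.07,37.8,0.139
pea,AOPH10,600,0.37,38.7,0.320
pea,AOPH10,1240,1.96,49.7,0.842
pea,AOPH10,1560,2.03,49.8,0.871
pea,886/01,300,0.08,41.7,0.146
pea,886/01,600,0.39,38.6,0.313
pea,886/01,1240,2.48,51.1,0.704
pea,886/01,1560,3.44,55.0,0.863
wheat,Caphorn,300,0.13,65.5,0.113
wheat,Caphorn,600,0.83,67.0,0.160
wheat,Caphorn,1240,1.00,64.3,0.652
wheat,Caphorn,1560,0.46,61.0,0.691
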