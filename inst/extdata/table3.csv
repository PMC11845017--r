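indicator,treatment,mean,se,letter
plant_height,CK,32.15,4.053,d
plant_height,Ab,51.36,2.93,abc
plant_height,Ce,41.69,7.08,cd
plant_height,Sv,59.16,2.89,ab
plant_height,Fm,61.43,0.34,a
plant_height,Ri,49.18,2.01,bc
plant_height,H,55.41,1.1,ab
root_length,CK,26.19,1.27,b
root_length,Ab,33.46,0.91,a
root_length,Ce,35.28,2.02,a
root_length,Sv,38.24,1.56,a
root_length,Fm,36.76,1.99,a
root_length,Ri,35.46,3.44,a
root_length,H,26.12,0.37,b
leaf_area,CK,586.6,10.54,c
leaf_area,Ab,682.71,30.89,ab
leaf_area,Ce,603.25,0.72,bc
leaf_area,Sv,696.82,26.04,a
leaf_area,Fm,680.47,35.59,ab
leaf_area,Ri,587.6,31.05,c
leaf_area,H,637.19,20.01,abc
stem_diameter,CK,4.43,0.09,b
stem_diameter,Ab,4.56,0.28,b
stem_diameter,Ce,4.53,0.17,b
stem_diameter,Sv,5.36,0.09,a
stem_diameter,Fm,5.24,0.13,a
stem_diameter,Ri,5.2833,0.09,a
stem_diameter,H,3.62,0.31,c
aboveground_biomass,CK,227.73,7.29,c
aboveground_biomass,Ab,365.58,32.22,ab
aboveground_biomass,Ce,296.41,27.22,bc
aboveground_biomass,Sv,392.24,3.91,a
aboveground_biomass,Fm,375.05,29.35,ab
aboveground_biomass,Ri,301.13,27.72,bc
aboveground_biomass,H,316.37,30.42,ab
belowground_biomass,CK,291.77,21.17,b
belowground_biomass,Ab,323.1,2.28,b
belowground_biomass,Ce,279.28,18.71,b
belowground_biomass,Sv,401.52,4.26,a
belowground_biomass,Fm,451.83,21.57,a
belowground_biomass,Ri,397.15,40.25,a
belowground_biomass,H,308.96,5.05,b
total_biomass,CK,519.5,20.25,d
total_biomass,Ab,688.68,33.64,b
total_biomass,Ce,575.69,8.93,cd
total_biomass,Sv,793.76,6.64,a
total_biomass,Fm,826.88,34.59,a
total_biomass,Ri,698.28,13.86,b
total_biomass,H,625.33,26.45,bc
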