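indicator,treatment,value
plant_height,CK,0
plant_height,Ab,0.66
plant_height,Ce,0.33
plant_height,Sv,0.92
plant_height,Fm,1
plant_height,Ri,0.58
plant_height,H,0.79
root_length,CK,0.01
root_length,Ab,0.61
root_length,Ce,0.76
root_length,Sv,1
root_length,Fm,0.88
root_length,Ri,0.77
root_length,H,0
leaf_area,CK,0
leaf_area,Ab,0.87
leaf_area,Ce,0.15
leaf_area,Sv,1
leaf_area,Fm,0.85
leaf_area,Ri,0.01
leaf_area,H,0.46
stem_diameter,CK,0.47
stem_diameter,Ab,0.54
stem_diameter,Ce,0.52
stem_diameter,Sv,1
stem_diameter,Fm,0.93
stem_diameter,Ri,0.96
stem_diameter,H,0
aboveground_biomass,CK,0
aboveground_biomass,Ab,0.84
aboveground_biomass,Ce,0.42
aboveground_biomass,Sv,1
aboveground_biomass,Fm,0.9
aboveground_biomass,Ri,0.45
aboveground_biomass,H,0.54
belowground_biomass,CK,0.07
belowground_biomass,Ab,0.25
belowground_biomass,Ce,0
belowground_biomass,Sv,0.71
belowground_biomass,Fm,1
belowground_biomass,Ri,0.68
belowground_biomass,H,0.17
total_biomass,CK,0
total_biomass,Ab,0.55
total_biomass,Ce,0.18
total_biomass,Sv,0.89
total_biomass,Fm,1
total_biomass,Ri,0.58
total_biomass,H,0.34
sod_activity,CK,0
sod_activity,Ab,0.53
sod_activity,Ce,0.82
sod_activity,Sv,0.91
sod_activity,Fm,0.33
sod_activity,Ri,0.19
sod_activity,H,0.74
pod_activity,CK,0
pod_activity,Ab,0.57
pod_activity,Ce,0.33
pod_activity,Sv,1
pod_activity,Fm,0.56
pod_activity,Ri,0.19
pod_activity,H,0.1
ppo_activity,CK,0
ppo_activity,Ab,0.51
ppo_activity,Ce,0.22
ppo_activity,Sv,1
ppo_activity,Fm,0.94
ppo_activity,Ri,0.66
ppo_activity,H,0.03
pal_activity,CK,0
pal_activity,Ab,0.6
pal_activity,Ce,0.58
pal_activity,Sv,0.61
pal_activity,Fm,0.82
pal_activity,Ri,1
pal_activity,H,0.14
iaa_content,CK,0
iaa_content,Ab,0.2
iaa_content,Ce,0.19
iaa_content,Sv,0.41
iaa_content,Fm,1
iaa_content,Ri,0.1
iaa_content,H,0.03
ctk_content,CK,0
ctk_content,Ab,0.05
ctk_content,Ce,0.56
ctk_content,Sv,0.98
ctk_content,Fm,1
ctk_content,Ri,0.22
ctk_content,H,0.27
chlorophyll_content,CK,0.47
chlorophyll_content,Ab,0.19
chlorophyll_content,Ce,0
chlorophyll_content,Sv,0.75
chlorophyll_content,Fm,1
chlorophyll_content,Ri,0.4
chlorophyll_content,H,0.32
soluble_sugar_content,CK,0
soluble_sugar_content,Ab,0.9
soluble_sugar_content,Ce,0.65
soluble_sugar_content,Sv,0.52
soluble_sugar_content,Fm,1
soluble_sugar_content,Ri,0.13
soluble_sugar_content,H,0.4
proline_content,CK,0
proline_content,Ab,1
proline_content,Ce,0.78
proline_content,Sv,0.77
proline_content,Fm,0.94
proline_content,Ri,0.2
proline_content,H,0.98
mda_content,CK,0
mda_content,Ab,0.79
mda_content,Ce,0.25
mda_content,Sv,1
mda_content,Fm,0.88
mda_content,Ri,0.77
mda_content,H,0.6
total_phenol_content,CK,0.24
total_phenol_content,Ab,0.76
total_phenol_content,Ce,0.99
total_phenol_content,Sv,1
total_phenol_content,Fm,0.94
total_phenol_content,Ri,0.11
total_phenol_content,H,0
flavonoids_content,CK,0
flavonoids_content,Ab,0.6
flavonoids_content,Ce,1
flavonoids_content,Sv,0.4
flavonoids_content,Fm,0.6
flavonoids_content,Ri,0.2
flavonoids_content,H,0.6
average_value,CK,0.07
average_value,Ab,0.58
average_value,Ce,0.46
average_value,Sv,0.83
average_value,Fm,0.87
average_value,Ri,0.43
average_value,H,0.34
rank,CK,7
rank,Ab,3
rank,Ce,4
rank,Sv,2
rank,Fm,1
rank,Ri,5
rank,H,6
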