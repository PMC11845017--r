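indicator,treatment,mean,se
sod_activity,CK,180,7.2
sod_activity,Ab,233,9.32
sod_activity,Ce,262,10.48
sod_activity,Sv,271,10.84
sod_activity,Fm,213,8.52
sod_activity,Ri,199,7.96
sod_activity,H,254,10.16
pod_activity,CK,300,12
pod_activity,Ab,374.1,14.964
pod_activity,Ce,342.9,13.716
pod_activity,Sv,430,17.2
pod_activity,Fm,372.8,14.912
pod_activity,Ri,324.7,12.988
pod_activity,H,313,12.52
ppo_activity,CK,50,2
ppo_activity,Ab,80.6,3.224
ppo_activity,Ce,63.2,2.528
ppo_activity,Sv,110,4.4
ppo_activity,Fm,106.4,4.256
ppo_activity,Ri,89.6,3.584
ppo_activity,H,51.8,2.072
pal_activity,CK,30,1.2
pal_activity,Ab,72,2.88
pal_activity,Ce,70.6,2.824
pal_activity,Sv,72.7,2.908
pal_activity,Fm,87.4,3.496
pal_activity,Ri,100,4
pal_activity,H,39.8,1.592
iaa_content,CK,20,0.8
iaa_content,Ab,24.4,0.976
iaa_content,Ce,24.18,0.9672
iaa_content,Sv,29.02,1.1608
iaa_content,Fm,42,1.68
iaa_content,Ri,22.2,0.888
iaa_content,H,20.66,0.8264
ctk_content,CK,95,3.8
ctk_content,Ab,96.25,3.85
ctk_content,Ce,109,4.36
ctk_content,Sv,119.5,4.78
ctk_content,Fm,120,4.8
ctk_content,Ri,100.5,4.02
ctk_content,H,101.75,4.07
chlorophyll_content,CK,1.782,0.0713
chlorophyll_content,Ab,1.614,0.0646
chlorophyll_content,Ce,1.5,0.06
chlorophyll_content,Sv,1.95,0.078
chlorophyll_content,Fm,2.1,0.084
chlorophyll_content,Ri,1.74,0.0696
chlorophyll_content,H,1.692,0.0677
soluble_sugar_content,CK,8,0.32
soluble_sugar_content,Ab,31.4,1.256
soluble_sugar_content,Ce,24.9,0.996
soluble_sugar_content,Sv,21.52,0.8608
soluble_sugar_content,Fm,34,1.36
soluble_sugar_content,Ri,11.38,0.4552
soluble_sugar_content,H,18.4,0.736
proline_content,CK,42,1.68
proline_content,Ab,52,2.08
proline_content,Ce,49.8,1.992
proline_content,Sv,49.7,1.988
proline_content,Fm,51.4,2.056
proline_content,Ri,44,1.76
proline_content,H,51.8,2.072
mda_content,CK,6.5,0.26
mda_content,Ab,3.735,0.1494
mda_content,Ce,5.625,0.225
mda_content,Sv,3,0.12
mda_content,Fm,3.42,0.1368
mda_content,Ri,3.805,0.1522
mda_content,H,4.4,0.176
total_phenol_content,CK,2.448,0.0979
total_phenol_content,Ab,3.852,0.1541
total_phenol_content,Ce,4.473,0.1789
total_phenol_content,Sv,4.5,0.18
total_phenol_content,Fm,4.338,0.1735
total_phenol_content,Ri,2.097,0.0839
total_phenol_content,H,1.8,0.072
flavonoids_content,CK,2,0.08
flavonoids_content,Ab,2.36,0.0944
flavonoids_content,Ce,2.6,0.104
flavonoids_content,Sv,2.24,0.0896
flavonoids_content,Fm,2.36,0.0944
flavonoids_content,Ri,2.12,0.0848
flavonoids_content,H,2.36,0.0944
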