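indicator,treatment,mean,se,letter
infection_rate,CK,8.89,1.11,e
infection_rate,Ab,26.43,1,d
infection_rate,Ce,48.3,1.21,c
infection_rate,Sv,92.22,4.01,a
infection_rate,Fm,100,0,a
infection_rate,Ri,81.11,4.44,b
infection_rate,H,52.03,3.93,c
infection_density,CK,0.68,0.04,e
infection_density,Ab,7.94,0.45,de
infection_density,Ce,15.68,0.66,cd
infection_density,Sv,35.87,3.35,b
infection_density,Fm,48.67,7.61,a
infection_density,Ri,22.88,4.78,c
infection_density,H,20.33,0.66,c
arbuscular_abundance,CK,0.07,0.03,d
arbuscular_abundance,Ab,7.9,0.4,cd
arbuscular_abundance,Ce,14.82,1.12,bc
arbuscular_abundance,Sv,20.34,3.54,b
arbuscular_abundance,Fm,36.91,6.16,a
arbuscular_abundance,Ri,14.08,4.99,bc
arbuscular_abundance,H,10.39,0.1,bcd
spore_density,CK,56,3.04,c
spore_density,Ab,245,20.57,b
spore_density,Ce,216,8.44,b
spore_density,Sv,241,20.36,b
spore_density,Fm,343.33,19.28,a
spore_density,Ri,259,25.46,b
spore_density,H,218,13.78,b
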