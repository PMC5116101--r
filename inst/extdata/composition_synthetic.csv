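group,energy_kj,iron_mg,calcium_mg,folate_dfe_ug,iodine_ug,zinc_mg
grains,500,0.8,20,30,5,0.7
vegetables,225,0.7,25,50,2,0.3
fruit,350,0.2,20,25,1,0.1
meat,550,1.5,50,10,10,2.5
dairy,550,0.05,280,10,30,0.6
fats_oils,250,0,2,0,0,0
discretionary,600,0.4,25,5,2,0.3
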