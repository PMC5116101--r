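product_id,iron_mg,calcium_mg,folic_acid_ug,iodine_ug,zinc_mg
prenatal_multi,60,125,800,220,11
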