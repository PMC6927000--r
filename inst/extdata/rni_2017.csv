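nutrient,trimester,lower,upper
energy_kcal,1,1680,1880
protein_g,1,53,90.5
carb_g,1,185,305.5
fat_g,1,54,65
fibre_g,1,20,30
vitA_RE,1,800,2800
vitC_mg,1,80,2000
vitB1_mg,1,1.4,
vitB2_mg,1,1.4,
vitB3_mg,1,18,35
sodium_mg,1,1500,2300
potassium_mg,1,4700,
calcium_mg,1,1000,2500
iron_mg,1,20,29
phosphorus_mg,1,700,3500
energy_kcal,2,1880,2080
protein_g,2,60.5,98
carb_g,2,210,338
fat_g,2,60,71
fibre_g,2,20,30
vitA_RE,2,800,2800
vitC_mg,2,80,2000
vitB1_mg,2,1.4,
vitB2_mg,2,1.4,
vitB3_mg,2,18,35
sodium_mg,2,1500,2300
potassium_mg,2,4700,
calcium_mg,2,1000,2500
iron_mg,2,20,29
phosphorus_mg,2,700,3500
energy_kcal,3,2070,2270
protein_g,3,77.5,115
carb_g,3,233.8,368.9
fat_g,3,65,78
fibre_g,3,20,30
vitA_RE,3,800,2800
vitC_mg,3,80,2000
vitB1_mg,3,1.4,
vitB2_mg,3,1.4,
vitB3_mg,3,18,35
sodium_mg,3,1500,2300
potassium_mg,3,4700,
calcium_mg,3,1000,2500
iron_mg,3,20,29
phosphorus_mg,3,700,3500
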