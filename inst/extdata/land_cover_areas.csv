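category,subcategory,level,area_km2,frac_of_category,frac_of_total
artificial,total,category_total,7973,NA,3
arable,livestock_production,subcategory,1986,9,NA
arable,organic_annual,subcategory,958,4,NA
arable,organic_perennial,subcategory,1212,5,NA
arable,mineral_all_crops,subcategory,18265,81,NA
arable,field_cultivation_total,subtotal,20435,91,NA
arable,total,category_total,22537,100,7
forest,mineral_soil,subcategory,174405,83,NA
forest,drained_peatland,subcategory,36725,17,NA
forest,total,category_total,211130,100,69
waterbody,river,subcategory,1388,4,NA
waterbody,lakes,subcategory,32510,96,NA
waterbody,total,category_total,33896,100,11
wetland,peat_production,subcategory,1026,3,NA
wetland,undrained_mires,subcategory,30508,97,NA
wetland,total,category_total,31534,100,10
total,total,grand_total,306954,NA,100
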