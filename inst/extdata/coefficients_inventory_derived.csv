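# Area-based emission coefficients, Gg gas km-2 yr-1 (gas mass, not CO2eq),
# DERIVED from the printed national flux totals divided by printed areas.
# The published per-size-class and per-mire-class coefficient tables are in
# a supplement not shipped here, so every class carries the national
# aggregate rate; class-resolved behaviour is exercised with synthetic
# coefficient tables instead.
category,subcategory,gas,zone,term,coefficient,sd,element,source
arable,organic_annual,CO2,national,total,2.90187891441,0.501043841336,,derived
arable,organic_perennial,CO2,national,total,2.08745874587,0.552805280528,,derived
arable,mineral_all_crops,CO2,national,total,0.0257322748426,0.0136873802354,,derived
waterbody,river,CO2,national,total,5.28097982709,0.864553314121,,derived
waterbody,lake_class_1,CO2,national,evasion,0.158720393725,0.0461396493387,,derived
waterbody,lake_class_1,CH4,national,diffusion,0.000566858549018,            0,,derived
waterbody,lake_class_1,CH4,national,ebullition,0.000377905699345,            0,,derived
waterbody,lake_class_2,CO2,national,evasion,0.158720393725,0.0461396493387,,derived
waterbody,lake_class_2,CH4,national,diffusion,0.000566858549018,            0,,derived
waterbody,lake_class_2,CH4,national,ebullition,0.000377905699345,            0,,derived
waterbody,lake_class_3,CO2,national,evasion,0.158720393725,0.0461396493387,,derived
waterbody,lake_class_3,CH4,national,diffusion,0.000566858549018,            0,,derived
waterbody,lake_class_3,CH4,national,ebullition,0.000377905699345,            0,,derived
waterbody,lake_class_4,CO2,national,evasion,0.158720393725,0.0461396493387,,derived
waterbody,lake_class_4,CH4,national,diffusion,0.000566858549018,            0,,derived
waterbody,lake_class_4,CH4,national,ebullition,0.000377905699345,            0,,derived
waterbody,lake_class_5,CO2,national,evasion,0.158720393725,0.0461396493387,,derived
waterbody,lake_class_5,CH4,national,diffusion,0.000566858549018,            0,,derived
waterbody,lake_class_5,CH4,national,ebullition,0.000377905699345,            0,,derived
waterbody,macrophyte_phragmites,CH4,national,total,0.000944764248363,            0,,derived
waterbody,macrophyte_equisetum,CH4,national,total,0.000944764248363,            0,,derived
wetland,mire_class_1,CH4,national,total,0.0134390979415,0.00209546910412,,derived
wetland,mire_class_1,N2O,national,total,0.000103900987307,            0,,derived
wetland,mire_class_1,CO2,national,total,-0.128163104759,0.0131113150649,,derived
wetland,mire_class_2,CH4,national,total,0.0134390979415,0.00209546910412,,derived
wetland,mire_class_2,N2O,national,total,0.000103900987307,            0,,derived
wetland,mire_class_2,CO2,national,total,-0.128163104759,0.0131113150649,,derived
wetland,mire_class_3,CH4,national,total,0.0134390979415,0.00209546910412,,derived
wetland,mire_class_3,N2O,national,total,0.000103900987307,            0,,derived
wetland,mire_class_3,CO2,national,total,-0.128163104759,0.0131113150649,,derived
wetland,mire_class_4,CH4,national,total,0.0134390979415,0.00209546910412,,derived
wetland,mire_class_4,N2O,national,total,0.000103900987307,            0,,derived
wetland,mire_class_4,CO2,national,total,-0.128163104759,0.0131113150649,,derived
forest,drained_peatland,CH4,national,total,0.000340367597005,            0,,derived
forest,drained_peatland,CO2,national,total,            0,            0,,derived
forest,drained_peatland,N2O,national,total,0.000147963574245,0.000361688737044,,derived
wetland,peat_production,CH4,national,total,0.00208855472013,            0,,derived
wetland,peat_production,CO2,national,total,1.75438596491,0.380116959064,,derived
wetland,peat_production,N2O,national,total,0.000331016219795,            0,,derived
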