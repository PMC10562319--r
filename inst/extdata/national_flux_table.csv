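category,source,level,ch4,co2,n2o,total,sd,intensity
artificial,industrial_processes,component,0,8.51,0,8.51,0.3,1.07
artificial,energy_waste_solids,component,0,6.49,0,6.49,0.13,0.81
artificial,energy_peat,component,0,5.76,0.04,5.8,0.2,0.73
artificial,energy_gaseous,component,0,5.72,0,5.72,1.59,0.72
artificial,energy_liquid,component,0,1.67,0,1.67,0.07,0.21
artificial,energy_biomass,component,0.01,0,0.09,0.1,0.05,0.01
artificial,energy_total,subtotal,0.01,19.63,0.13,19.77,0.59,2.48
artificial,road_traffic,component,0,10.37,0,10.37,0.31,1.3
artificial,machinery,component,0,3.16,0,3.16,0.19,0.4
artificial,waste_management,component,1.88,0,0.1,1.98,0.7,0.25
artificial,residential_combustion,component,0.19,1.66,0.03,1.88,0.44,0.24
artificial,total_emission,category_emission,2.08,43.34,0.26,45.68,1.97,5.73
arable,livestock_production,component,2.8,0,0.24,3.04,2.28,1.53
arable,field_cultivation,component,0,0.2,3.22,3.43,2.57,0.17
arable,organic_annual,component,0,2.78,0,2.78,0.48,2.9
arable,organic_perennial,component,0,2.53,0,2.53,0.67,2.09
arable,mineral_all_crops,component,0,0.47,0,0.47,0.25,0.03
arable,total_emission,category_emission,2.8,5.98,3.47,12.24,3.54,0.55
forest,timber_mineral,component,0,44.75,0,44.75,3.12,0.26
forest,timber_drained_peat,component,0,8.84,0,8.84,0.49,0.24
forest,timber_total,subtotal,0,53.6,0,53.6,3.16,0.25
forest,energywood_mineral,component,0,5.23,0,5.23,0.89,0.03
forest,energywood_drained_peat,component,0,0.99,0,0.99,0.14,0.03
forest,energywood_total,subtotal,0,6.22,0,6.22,0.9,0.03
forest,harvest_total,subtotal,0,59.82,0,59.82,3.29,0.28
forest,drained_peat_soil,component,0.35,0,1.44,1.79,3.52,0.05
forest,total_emission,category_emission,0.35,59.82,1.44,61.61,4.81,0.29
forest,ecosystems_mineral_soil,sink_component,NA,-79.87,NA,-79.87,12.2,-0.38
forest,ecosystems_drained_peat,sink_component,NA,-9.41,NA,-9.41,6.1,-0.04
forest,total_sink,category_sink,NA,-89.28,NA,-89.28,13.7,-0.42
forest,net_emission,category_net,0.35,-29.47,1.44,-27.68,10.3,-0.13
waterbody,rivers,component,0,7.33,0,7.33,1.2,5.28
waterbody,lakes,component,0.86,5.16,0,6.02,1.5,0.19
waterbody,total_emission,category_emission,0.86,12.49,0,13.35,1.92,0.39
wetland,peat_production,component,0.06,1.8,0.09,1.95,0.39,1.9
wetland,mire_soil,component,11.48,0,0.84,12.32,1.79,0.4
wetland,total_emission,category_emission,11.54,1.8,0.93,14.27,1.84,0.45
wetland,mire_ecosystems,sink_component,NA,-3.91,NA,-3.91,0.4,0
wetland,total_sink,category_sink,NA,-3.91,NA,-3.91,0.4,0
wetland,net_emission,category_net,11.54,-2.11,0.93,10.36,4.4,0.34
total,total_emission,grand_emission,17.63,123.43,6.1,147.16,6.83,0.48
total,net_emission,grand_net,17.63,30.23,6.1,53.9,15.3,0.18
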