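station_id,depth_m,layer_top_cm,layer_bottom_cm,target,copies_per_mg,sd
10,360,0,2,denitrifier_nirS,2970,310
10,360,0,2,anammox_nirS,30,12
04,680,0,2,denitrifier_nirS,4100,450
04,680,0,2,anammox_nirS,215,40
16,970,0,2,denitrifier_nirS,7245,813
16,970,0,2,anammox_nirS,1728,198
16,970,6,8,denitrifier_nirS,820,120
16,970,6,8,anammox_nirS,n.d.,NA
08,1430,0,2,denitrifier_nirS,439,90
08,1430,0,2,anammox_nirS,203,44
08,1430,2,4,denitrifier_nirS,610,95
08,1430,2,4,anammox_nirS,93,44
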