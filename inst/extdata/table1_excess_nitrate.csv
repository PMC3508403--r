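station_id,layer_top_cm,layer_bottom_cm,excess_no3_nmol_cm3
10,0,2,95.8
10,2,4,22.2
10,4,6,12.3
10,6,8,n.d.
04,0,2,110.6
04,2,4,23.6
04,4,6,3.1
04,6,8,n.d.
16,0,2,222.0
16,2,4,n.d.
16,4,6,n.d.
16,6,8,n.d.
08,0,2,111.6
08,2,4,n.d.
08,4,6,n.d.
08,6,8,n.d.
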