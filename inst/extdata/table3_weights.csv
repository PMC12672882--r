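criterion,weight_pct
Access points,10.0
Pathways,10.4
Facilities for different activities,14.3
Open space,16.3
Amenities,13.5
Natural features,14.0
Sunlight,11.0
Incivilities,10.6
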