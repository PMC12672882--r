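case,Access points,Pathways,Facilities for different activities,Open space,Amenities,Natural features,Sunlight,Incivilities,synthesized_gap,rank,corrupted
1,0.050,0.042,0.073,0.067,0.076,0.046,0.036,0.026,0.245,7,FALSE
2,0.048,0.045,0.080,0.077,0.072,0.040,0.034,0.027,0.252,8,FALSE
3,0.039,0.037,0.057,0.039,0.054,0.035,0.026,0.024,0.184,2,FALSE
4,0.039,0.032,0.075,0.035,0.062,0.032,0.031,0.019,0.200,3,FALSE
5,0.030,0.029,0.046,0.013,0.055,0.040,0.030,0.019,0.158,1,FALSE
6,0.036,0.028,0.059,0.074,0.059,0.043,0.033,0.019,0.213,6,FALSE
7,0.042,0.041,0.070,0.038,0.057,0.044,0.030,0.024,0.208,4,FALSE
8,0.040,0.039,0.063,0.055,0.057,0.050,0.037,0.020,0.212,5,FALSE
9,0.050,0.042,0.073,0.067,0.076,0.046,0.036,0.026,0.329,9,TRUE
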