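method,Modified VIKOR,VIKOR,SAW,TOPSIS,PROMETHEE II,EXPERT
Modified VIKOR,1,0.833,0.983,1.000,0.900,0.800
VIKOR,0.833,1,0.817,0.833,0.867,0.783
SAW,0.983,0.817,1,0.983,0.950,0.867
TOPSIS,1.000,0.833,0.983,1,0.900,0.800
PROMETHEE II,0.900,0.867,0.950,0.900,1,0.933
EXPERT,0.800,0.783,0.867,0.800,0.933,1
Average correlation,0.920,0.856,0.933,0.920,0.925,0.864
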