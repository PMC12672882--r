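case,mv_performance,mv_rank,vikor_performance,vikor_rank,saw_performance,saw_rank,topsis_performance,topsis_rank,promethee_performance,promethee_rank,expert_performance,expert_rank
1,0.245,7,0.687,8,0.586,3,0.468,3,-1.816,3,6.261,2
2,0.252,8,0.633,7,0.577,2,0.410,2,-1.853,2,6.522,3
3,0.184,2,0.159,2,0.690,8,0.761,8,1.873,8,7.391,6
4,0.200,3,0.378,6,0.676,7,0.701,7,1.270,6,7.565,7
5,0.158,1,0.000,1,0.740,9,0.937,9,3.252,9,8.087,9
6,0.213,6,0.359,4,0.649,5,0.542,4,1.305,7,7.783,8
7,0.208,4,0.370,5,0.655,6,0.680,6,0.576,5,7.261,5
8,0.212,5,0.305,3,0.641,4,0.608,5,0.482,4,6.913,4
9,0.329,9,1.000,9,0.463,1,0.027,1,-5.089,1,5.043,1
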