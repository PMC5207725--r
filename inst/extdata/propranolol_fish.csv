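fish_id,percent_depletion,percent_depletion_sd,k_h,t_half_h,letters
1,24,5,0.010,70.0,D
2,36,9,0.017,40.3,"C,D"
3,39,10,0.020,34.1,"B,C"
4,68,11,0.045,15.5,A
5,39,5,0.019,36.5,"B,C"
6,51,12,0.027,25.7,"A,B,C"
7,34,4,0.018,39.6,"C,D"
8,56,5,0.032,21.6,"A,B"
9,34,4,0.017,41.0,"C,D"
10,52,6,0.029,23.7,"A,B,C"
11,50,7,0.029,24.0,"A,B,C"
12,15,5,0.007,100.4,E
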