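rank,formula_text,K,logL,AIC,delta_AIC,akaike_weight
1,snowfall_category * time_of_day + snow_depth,16,-10769.14,21570.28,0.00,0.62
2,snowfall_category * time_of_day,15,-10770.63,21571.25,0.97,0.38
3,snowfall_category + time_of_day + snow_depth,10,-10787.63,21595.25,24.97,0.00
4,snowfall_category + time_of_day,9,-10789.12,21596.24,25.96,0.00
5,time_of_day + snow_depth,4,-10799.45,21606.90,36.62,0.00
6,time_of_day,3,-10800.63,21607.26,36.98,0.00
7,snowfall_category + snow_depth,9,-10796.56,21611.13,40.85,0.00
8,snowfall_category * time_of_day + snow_depth,8,-10798.37,21612.73,42.45,0.00
9,snow_depth,3,-10808.26,21622.53,52.25,0.00
10,Null model,2,-10809.69,21623.37,53.09,0.00
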