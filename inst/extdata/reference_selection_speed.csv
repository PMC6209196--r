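rank,formula_text,K,logL,AIC,delta_AIC,akaike_weight
1,snowfall_category + time_of_day,12,-3501.96,7027.93,0.00,0.51
2,snowfall_category * time_of_day,18,-3496.88,7029.75,1.82,0.20
3,snowfall_category + time_of_day + snow_depth,13,-3501.95,7029.90,1.98,0.19
4,snowfall_category * time_of_day + snow_depth,19,-3496.85,7031.71,3.78,0.08
5,time_of_day,6,-3511.88,7035.76,7.83,0.01
6,snowfall_category,11,-3507.28,7036.55,8.62,0.01
7,time_of_day + snow_depth,7,-3511.75,7037.50,9.57,0.00
8,snowfall_category + snow_depth,12,-3507.26,7038.52,10.60,0.00
9,Null model,5,-3517.27,7044.54,16.61,0.00
10,snow_depth,6,-3517.15,7046.30,18.37,0.00
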