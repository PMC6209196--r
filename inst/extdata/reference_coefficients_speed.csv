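term,beta,se,transformed,ci_lower,ci_upper
Intercept,1.081,0.026,12.049,10.701,13.609
time_of_day: night,0.107,0.028,1.280,1.130,1.459
snowfall_category: control,0.061,0.023,1.152,1.037,1.273
snowfall_category: two_before,0.037,0.023,1.088,0.981,1.211
snowfall_category: one_before,0.045,0.021,1.110,1.006,1.222
snowfall_category: one_after,0.005,0.022,1.012,0.914,1.116
snowfall_category: two_after,0.041,0.022,1.099,0.995,1.210
snowfall_category: three_after,-0.016,0.022,0.964,0.874,1.064
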