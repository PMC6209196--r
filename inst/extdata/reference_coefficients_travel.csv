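term,beta,se,transformed,ci_lower,ci_upper
Intercept,-0.467,0.079,0.627,0.544,0.725
time_of_day: night,-0.542,0.086,0.582,0.507,0.664
night x control,0.563,0.125,1.756,1.425,2.187
night x two_before,0.456,0.130,1.578,1.267,1.969
night x one_before,0.365,0.121,1.440,1.172,1.771
night x one_after,0.268,0.123,1.307,1.063,1.608
night x two_after,0.621,0.123,1.862,1.507,2.316
night x three_after,0.546,0.122,1.726,1.410,2.138
snowfall_category: control,-0.243,0.096,0.784,0.658,0.926
snowfall_category: two_before,-0.201,0.100,0.818,0.681,0.975
snowfall_category: one_before,-0.026,0.094,0.974,0.821,1.153
snowfall_category: one_after,-0.025,0.094,0.975,0.82,1.159
snowfall_category: two_after,-0.169,0.096,0.845,0.709,1.006
snowfall_category: three_after,-0.095,0.095,0.909,0.763,1.074
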