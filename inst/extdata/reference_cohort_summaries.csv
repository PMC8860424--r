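feature,n_spch,mean_spch,sd_spch,n_lpa,mean_lpa,sd_lpa,p_reported
skewness,13,1.413,0.773,49,1.227,0.511,0.302
kurtosis,13,4.888,3.70,49,3.406,1.415,0.026
p75,13,87.75,33.976,49,80.505,30.563,0.461
p975,13,128.55,54.810,49,100.971,35.913,0.106
uniformity,13,0.0173,0.005,49,0.029,0.011,<0.001
autocorrelation,13,54.450,43.098,49,215.698,186.057,<0.001
contrast,13,5.179,4.420,49,3.667,3.529,0.198
correlation,13,0.501,0.091,49,0.636,0.121,<0.001
cluster_prominence,13,973.146,982.489,49,2051.079,5967.805,0.521
cluster_shade,13,-8.520,60.754,49,62.069,168.781,0.145
dissimilarity,13,1.546,0.742,49,1.255,0.719,0.202
energy,13,0.049,0.026,49,0.066,0.062,0.141
entropy,13,3.512,0.579,49,3.470,0.955,0.844
inverse_difference,13,0.554,0.099,49,0.603,0.136,0.230
inverse_difference_moment,13,0.505,0.121,49,0.563,0.165,0.242
maximum_probability,13,0.114,0.044,49,0.127,0.109,0.518
sum_of_squares_variance,13,57.70,45.249,49,216.875,186.892,<0.001
sum_average,13,13.245,5.961,49,25.005,15.119,<0.001
sum_variance,13,160.969,142.297,49,735.150,651.642,<0.001
sum_entropy,13,2.481,0.347,49,2.492,0.526,0.930
difference_variance,13,5.179,4.420,49,3.667,3.529,0.198
difference_entropy,13,1.487,0.341,49,1.306,0.415,0.153
imc1,13,-0.170,0.052,49,-0.197,0.075,0.234
imc2,13,0.663,0.099,49,0.685,0.106,0.507
inverse_difference_normalized,13,0.994,0.003,49,0.995,0.003,0.202
inverse_difference_moment_normalized,13,0.999,0.00007,49,0.999,0.00005,0.202
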