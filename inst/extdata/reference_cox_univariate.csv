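feature,hr,beta,ci_lower,ci_upper,p
Mean_HLL,1.028,0.027,1.012,1.044,0.001
Median_HHL,2.977,1.091,1.548,5.726,0.001
Mean_absolute_deviation_HLL,1.011,0.011,1.003,1.019,0.007
RunPercentage_HLL,1.300,0.263,1.066,1.586,0.010
Range_HLH,1.001,0.001,1.000,1.002,0.013
Surface_to_volume_ratio,210.673,5.352,2.872,15475.144,0.015
Entropy_group1,0.349,-1.052,0.149,0.817,0.015
Median_HLH,1175.998,7.070,3.749,368844.040,0.016
Energy_HLL,1.000,0.000,1.000,1.000,0.019
Mean_HHL,1.189,0.173,1.025,1.380,0.023
Variance_HLL,1.000,0.000,1.000,1.000,0.029
Dissimilarity_HLL,1.759,0.565,1.051,2.944,0.032
Root_mean_square_HLL,1.007,0.007,1.000,1.014,0.037
Maximum_HLH,1.001,0.001,1.000,1.003,0.047
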