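variable,uni_hr,uni_ci_lower,uni_ci_upper,uni_p,multi_hr,multi_ci_lower,multi_ci_upper,multi_p
Sex_Female_vs_Male,0.722,0.363,1.439,0.355,0.870,0.428,1.767,0.699
Age,0.978,0.944,1.012,0.202,0.991,0.959,1.024,0.567
WHO_Grade_II_vs_III,0.337,0.177,0.643,0.001,0.420,0.213,0.827,0.012
IDH_MUT_vs_WT,0.402,0.209,0.770,0.006,0.538,0.269,1.078,0.081
Risk_Score_Low_vs_High,0.806,0.727,0.894,0.0005,0.875,0.780,0.981,0.022
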