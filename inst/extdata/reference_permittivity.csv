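tissue,frequency_ghz,eps_real_model,eps_real_ref,delta_real_pct,eps_imag_model,eps_imag_ref,delta_imag_pct
muscle,1,50.98,53.91,5.435,2.560,2.910,12.03
muscle,3,49.46,51.55,4.054,6.511,7.511,13.31
muscle,5,47.60,49.23,3.311,9.791,11.30,13.35
muscle,10,42.16,42.61,1.056,15.46,17.60,12.16
muscle,20,31.86,30.86,3.240,19.78,21.41,7.613
liver,1,44.75,42.34,5.692,2.281,2.790,18.24
liver,3,43.48,40.49,7.384,5.650,6.771,16.55
liver,5,41.87,38.27,9.407,8.470,10.21,17.04
liver,10,37.14,31.74,17.01,13.43,14.81,9.318
liver,20,28.11,22.01,27.71,17.27,16.59,4.099
heart,1,63.33,53.25,18.93,3.210,3.251,1.261
heart,3,61.47,51.17,20.13,8.230,8.220,0.1216
heart,5,59.13,48.53,21.84,12.28,12.11,1.404
heart,10,52.24,41.02,27.35,19.54,18.21,7.304
heart,20,39.77,29.65,34.13,25.15,21.35,17.79
kidney,1,49.06,50.30,2.465,2.431,3.050,20.29
kidney,3,47.66,48.35,1.427,6.250,7.700,18.83
kidney,5,45.87,45.89,0.0438,9.370,11.44,18.09
kidney,10,40.64,39.06,4.045,14.84,17.05,12.96
kidney,20,31.01,27.70,11.94,19.04,20.06,5.085
fat,1,3.91,5.39,27.5,0.0760,0.250,69.6
fat,3,3.87,5.21,25.7,0.191,0.521,63.3
fat,5,3.82,5.00,23.6,0.290,0.721,59.8
fat,10,3.65,4.59,20.5,0.467,0.970,51.8
fat,20,3.35,4.01,16.5,0.601,1.092,44.9
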