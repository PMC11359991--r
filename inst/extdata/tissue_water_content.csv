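tissue,wc_mass_pct,wc_mass_sd_pct,wc_vol_pct,wc_vol_unc_pct,literature_vol_pct
muscle,70.8,0.700,75.2,5.22,73-78
liver,74.4,1.60,70.1,5.47,73-77
heart,79.3,0.230,87.9,6.52,86-87
kidney,65.1,3.99,73.1,5.31,78-79
fat,6.20,0.620,5.20,10.9,5-20
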