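tmp_bar,temperature_K,c_feed_mol_L,c_permeate_mol_L,jv_L_m2_h,jv_sd_L_m2_h,series,rejection_pct,rejection_sd_pct
4.5,293.15,NA,NA,9.8,1.0,tyrosol,73.1,6.2
9.5,293.15,NA,NA,14.4,0.8,tyrosol,82.5,0.9
14.5,293.15,NA,NA,28.1,0.7,tyrosol,55.7,1.2
4.5,298.15,NA,NA,11.3,0.9,tyrosol,70.3,2.6
9.5,298.15,NA,NA,18.1,2.9,tyrosol,27.6,1.9
14.5,298.15,NA,NA,31.2,0.2,tyrosol,55.7,1.4
4.5,303.15,NA,NA,13.1,1.3,tyrosol,59.3,2.1
9.5,303.15,NA,NA,18.6,2.1,tyrosol,69.9,2.6
14.5,303.15,NA,NA,32.6,4.3,tyrosol,62.9,1.8
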