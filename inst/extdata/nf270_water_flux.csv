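tmp_bar,temperature_K,c_feed_mol_L,c_permeate_mol_L,jv_L_m2_h,jv_sd_L_m2_h,series
4.5,293.15,0,0,49.1,1.0,water-I
9.5,293.15,0,0,87.0,0.8,water-I
14.5,293.15,0,0,108.1,0.7,water-I
4.5,298.15,0,0,59.2,0.9,water-I
9.5,298.15,0,0,111.2,3.9,water-I
14.5,298.15,0,0,156.3,0.2,water-I
4.5,303.15,0,0,70.6,1.3,water-I
9.5,303.15,0,0,123.0,2.1,water-I
14.5,303.15,0,0,170.2,4.3,water-I
4.5,293.15,0,0,14.5,0.9,water-II
9.5,293.15,0,0,28.5,0.9,water-II
14.5,293.15,0,0,40.3,0.8,water-II
4.5,298.15,0,0,17.7,0.9,water-II
9.5,298.15,0,0,32.4,0.9,water-II
14.5,298.15,0,0,47.9,1.0,water-II
4.5,303.15,0,0,21.1,0.8,water-II
9.5,303.15,0,0,40.8,1.1,water-II
14.5,303.15,0,0,57.1,1.5,water-II
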