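tmp_bar,temperature_K,c_feed_mol_L,c_permeate_mol_L,jv_L_m2_h,jv_sd_L_m2_h,series
4.5,293.15,1.47e-2,7.03e-4,4.7,0.2,C1
4.5,298.15,2.18e-2,14.65e-4,4.8,0.1,C1
4.5,303.15,1.47e-2,11.10e-4,6.7,0.3,C1
4.5,308.15,1.47e-2,11.69e-4,6.5,0.3,C1
9.5,293.15,1.47e-2,8.18e-4,10.7,0.4,C1
9.5,298.15,2.25e-2,12.40e-4,12.3,0.8,C1
9.5,303.15,1.47e-2,9.64e-4,14.9,0.6,C1
9.5,308.15,1.47e-2,10.35e-4,16.4,0.6,C1
14.5,293.15,1.47e-2,6.24e-4,16.5,0.7,C1
14.5,298.15,2.53e-2,10.48e-4,17.5,1.3,C1
14.5,303.15,1.47e-2,8.65e-4,23.9,0.6,C1
14.5,308.15,1.47e-2,8.51e-4,26.1,0.8,C1
19.5,298.15,1.95e-2,7.18e-4,24.7,0.7,C1
4.5,293.15,5.45e-3,4.74e-4,10.0,0.3,C2
4.5,298.15,8.66e-3,6.12e-4,13.4,0.6,C2
4.5,303.15,5.25e-3,4.53e-4,17.7,0.4,C2
4.5,308.15,4.39e-3,2.96e-4,20.5,0.5,C2
9.5,293.15,5.45e-3,4.41e-4,22.5,0.9,C2
9.5,298.15,7.03e-3,4.42e-4,26.8,1.3,C2
9.5,303.15,5.18e-3,2.94e-4,34.9,0.9,C2
9.5,308.15,4.49e-3,3.06e-4,39.1,1.0,C2
14.5,293.15,5.25e-3,2.27e-4,34.1,1.1,C2
14.5,298.15,6.19e-3,4.22e-4,36.0,2.2,C2
14.5,303.15,5.18e-3,3.90e-4,44.1,1.7,C2
14.5,308.15,4.49e-3,2.66e-4,51.3,1.5,C2
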