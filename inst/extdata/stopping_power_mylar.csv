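# Total (collision + radiative) mass stopping power for electrons in
# Mylar (PET), transcribed independently of the water table on its own
# energy grid. Mylar and water agree within ~2% over 0.1-100 MeV, which
# is what makes the water-equivalent transport assumption tenable; this
# second tabulation doubles as an interpolation cross-check.
# material=mylar
energy_MeV,total_sp_MeV_cm2_g
0.012,19.29
0.018,14.08
0.025,10.94
0.040,7.685
0.060,5.776
0.080,4.751
0.120,3.648
0.180,2.913
0.250,2.516
0.400,2.151
0.600,1.965
0.800,1.888
1.200,1.825
1.800,1.819
2.500,1.842
3.500,1.878
4.500,1.916
6.000,1.975
8.000,2.050
12.00,2.194
18.00,2.373
25.00,2.577
35.00,2.844
45.00,3.107
60.00,3.509
80.00,4.027
120.0,5.087
150.0,5.861
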