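# Total (collision + radiative) mass stopping power for electrons in
# liquid water, transcribed from the public ESTAR tabulation at 3-4
# significant figures. Used as the water-equivalent table for all beamline
# materials (Mylar, RCF, PEEK, water have near-identical stopping powers).
# material=water
energy_MeV,total_sp_MeV_cm2_g
0.010,22.56
0.015,16.47
0.020,13.17
0.030,9.660
0.050,6.610
0.070,5.300
0.100,4.120
0.150,3.250
0.200,2.800
0.300,2.370
0.500,2.050
0.700,1.950
1.000,1.862
1.500,1.841
2.000,1.850
3.000,1.886
4.000,1.925
5.000,1.964
7.000,2.040
10.00,2.151
15.00,2.324
20.00,2.460
30.00,2.751
40.00,3.010
50.00,3.290
70.00,3.810
100.0,4.600
150.0,5.950
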