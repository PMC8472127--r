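# Mass attenuation coefficient of copper, mu/rho in cm^2/g, transcribed
# from the standard NIST tabulation. Density 8.96 g/cm^3. Log-log
# interpolation between grid points. Covers 10-200 keV (above the Cu
# K-edge at 8.98 keV).
energy_keV,mu_over_rho_cm2_per_g
10,215.9
15,74.05
20,33.79
30,10.92
40,4.862
50,2.613
60,1.593
80,0.763
100,0.4584
150,0.2217
200,0.1559
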