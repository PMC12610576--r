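# material: AL
# density_g_cm3: 2.699
# z_over_a: 0.48181
# units: energy keV; coefficients cm^2/g (mass attenuation; mu_en = mass energy absorption)
# energy_kev photoelectric compton rayleigh total
5.0e+00 1.92971e+02 1.89339e-01 2.39516e-01 1.934e+02
6.0e+00 1.14872e+02 1.88624e-01 2.39516e-01 1.153e+02
8.0e+00 4.99033e+01 1.87216e-01 2.39516e-01 5.033e+01
1.0e+01 2.58046e+01 1.85834e-01 2.39516e-01 2.623e+01
1.5e+01 7.61576e+00 1.82495e-01 1.56750e-01 7.955e+00
2.0e+01 3.17094e+00 1.79311e-01 9.07450e-02 3.441e+00
3.0e+01 9.12635e-01 1.73365e-01 4.20000e-02 1.128e+00
4.0e+01 3.76263e-01 1.67922e-01 2.43145e-02 5.685e-01
5.0e+01 1.89265e-01 1.62923e-01 1.59124e-02 3.681e-01
6.0e+01 1.08233e-01 1.58313e-01 1.12536e-02 2.778e-01
8.0e+01 4.51933e-02 1.50092e-01 6.51491e-03 2.018e-01
1.0e+02 2.31640e-02 1.42972e-01 4.26363e-03 1.704e-01
1.5e+02 7.11329e-03 1.28713e-01 1.97336e-03 1.378e-01
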