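# material: PMMA
# density_g_cm3: 1.19
# z_over_a: 0.53937
# units: energy keV; coefficients cm^2/g (mass attenuation; mu_en = mass energy absorption)
# energy_kev photoelectric compton rayleigh total
5.0e+00 2.36797e+01 2.11959e-01 1.08353e-01 2.400e+01
6.0e+00 1.36805e+01 2.11159e-01 1.08353e-01 1.400e+01
8.0e+00 5.78207e+00 2.09582e-01 1.08353e-01 6.100e+00
1.0e+01 3.04061e+00 2.08035e-01 1.08353e-01 3.357e+00
1.5e+01 8.25792e-01 2.04297e-01 7.09105e-02 1.101e+00
2.0e+01 3.29616e-01 2.00732e-01 4.10513e-02 5.714e-01
3.0e+01 9.01243e-02 1.94076e-01 1.90000e-02 3.032e-01
4.0e+01 3.60170e-02 1.87984e-01 1.09994e-02 2.350e-01
5.0e+01 1.78150e-02 1.82387e-01 7.19848e-03 2.074e-01
6.0e+01 1.00829e-02 1.77226e-01 5.09092e-03 1.924e-01
8.0e+01 4.13009e-03 1.68023e-01 2.94722e-03 1.751e-01
1.0e+02 2.11852e-03 1.60053e-01 1.92879e-03 1.641e-01
1.5e+02 6.17050e-04 1.44090e-01 8.92710e-04 1.456e-01
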