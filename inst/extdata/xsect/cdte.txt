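# material: CDTE
# density_g_cm3: 5.85
# z_over_a: 0.41665
# units: energy keV; coefficients cm^2/g (mass attenuation; mu_en = mass energy absorption)
# energy_kev photoelectric compton rayleigh total
5.000e+00 6.47270e+02 1.63733e-01 2.56625e+00 6.50e+02
6.000e+00 3.97271e+02 1.63115e-01 2.56625e+00 4.00e+02
8.000e+00 2.22272e+02 1.61897e-01 2.56625e+00 2.25e+02
1.000e+01 1.21273e+02 1.60702e-01 2.56625e+00 1.24e+02
1.500e+01 3.91627e+01 1.57815e-01 1.67946e+00 4.10e+01
2.000e+01 1.69727e+01 1.55061e-01 9.72268e-01 1.81e+01
2.670e+01 7.98691e+00 1.51564e-01 5.61528e-01 8.70e+00
2.672e+01 2.47877e+01 1.51554e-01 5.60730e-01 2.55e+01
3.000e+01 1.84001e+01 1.49919e-01 4.50000e-01 1.90e+01
3.180e+01 1.55481e+01 1.49041e-01 4.02839e-01 1.61e+01
3.182e+01 2.88486e+01 1.49031e-01 4.02358e-01 2.94e+01
4.000e+01 1.61943e+01 1.45213e-01 2.60513e-01 1.66e+01
5.000e+01 8.98862e+00 1.40889e-01 1.70490e-01 9.30e+00
6.000e+01 5.24252e+00 1.36903e-01 1.20575e-01 5.50e+00
8.000e+01 2.44040e+00 1.29793e-01 6.98027e-02 2.64e+00
1.000e+02 1.24068e+00 1.23637e-01 4.56818e-02 1.41e+00
1.500e+02 3.97551e-01 1.11306e-01 2.11431e-02 5.30e-01
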