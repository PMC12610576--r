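# material: AIR
# density_g_cm3: 0.001205
# z_over_a: 0.49919
# units: energy keV; coefficients cm^2/g (mass attenuation; mu_en = mass energy absorption)
# energy_kev photoelectric compton rayleigh total mu_en
5.0e+00 3.99512e+01 1.96169e-01 1.22610e-01 4.027e+01 3.890e+01
6.0e+00 2.30920e+01 1.95429e-01 1.22610e-01 2.341e+01 2.280e+01
8.0e+00 9.60442e+00 1.93969e-01 1.22610e-01 9.921e+00 9.446e+00
1.0e+01 4.80485e+00 1.92538e-01 1.22610e-01 5.120e+00 4.742e+00
1.5e+01 1.34468e+00 1.89078e-01 8.02408e-02 1.614e+00 1.334e+00
2.0e+01 5.45668e-01 1.85779e-01 4.64528e-02 7.779e-01 5.389e-01
3.0e+01 1.52682e-01 1.79618e-01 2.15000e-02 3.538e-01 1.537e-01
4.0e+01 6.20734e-02 1.73980e-01 1.24467e-02 2.485e-01 6.833e-02
5.0e+01 3.10546e-02 1.68800e-01 8.14565e-03 2.080e-01 4.098e-02
6.0e+01 1.77154e-02 1.64024e-01 5.76078e-03 1.875e-01 3.041e-02
8.0e+01 7.35904e-03 1.55506e-01 3.33502e-03 1.662e-01 2.407e-02
1.0e+02 3.78775e-03 1.48130e-01 2.18257e-03 1.541e-01 2.325e-02
1.5e+02 1.23349e-03 1.33356e-01 1.01017e-03 1.356e-01 2.496e-02
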