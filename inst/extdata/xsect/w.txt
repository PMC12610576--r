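# material: W
# density_g_cm3: 19.3
# z_over_a: 0.4025
# units: energy keV; coefficients cm^2/g (mass attenuation; mu_en = mass energy absorption)
# energy_kev photoelectric compton rayleigh total
5.000e+00 7.75850e+02 1.58172e-01 3.99194e+00 7.800e+02
6.000e+00 4.65850e+02 1.57575e-01 3.99194e+00 4.700e+02
8.000e+00 1.85852e+02 1.56398e-01 3.99194e+00 1.900e+02
1.000e+01 9.27628e+01 1.55244e-01 3.99194e+00 9.691e+01
1.020e+01 9.08529e+01 1.55130e-01 3.99194e+00 9.500e+01
1.022e+01 2.80853e+02 1.55119e-01 3.99194e+00 2.850e+02
1.200e+01 1.90854e+02 1.54112e-01 3.99194e+00 1.950e+02
1.500e+01 1.36235e+02 1.52455e-01 2.61249e+00 1.390e+02
2.000e+01 6.40678e+01 1.49795e-01 1.51242e+00 6.573e+01
3.000e+01 2.18852e+01 1.44827e-01 7.00000e-01 2.273e+01
4.000e+01 1.01245e+01 1.40281e-01 4.05242e-01 1.067e+01
5.000e+01 5.54769e+00 1.36104e-01 2.65207e-01 5.949e+00
6.000e+01 3.39319e+00 1.32253e-01 1.87560e-01 3.713e+00
6.952e+01 2.28936e+00 1.28856e-01 1.41782e-01 2.560e+00
6.953e+01 1.11294e+01 1.28853e-01 1.41743e-01 1.140e+01
8.000e+01 7.57603e+00 1.25385e-01 1.08582e-01 7.810e+00
1.000e+02 4.24750e+00 1.19438e-01 7.10605e-02 4.438e+00
1.500e+02 1.44058e+00 1.07526e-01 3.28893e-02 1.581e+00
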