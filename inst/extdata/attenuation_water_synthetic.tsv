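# synthetic photon attenuation table: water
# density_g_cm3: 1.000
# columns: E_keV, mu_photo, mu_compton, mu_pair (linear coefficients, per mm)
# computed analytically (Klein-Nishina closed form; power-law photoelectric
# calibrated on lead anchors; pair production Z^2-scaled from standard water
# totals); coherent scattering omitted. See scripts/make_attenuation_tables.R
E_keV	mu_photo	mu_compton	mu_pair
1.000e+01	5.73557e-02	2.14100e-02	0.00000e+00
1.500e+01	2.05620e-02	2.10253e-02	0.00000e+00
2.000e+01	9.93049e-03	2.06584e-02	0.00000e+00
3.000e+01	3.56008e-03	1.99733e-02	0.00000e+00
4.000e+01	1.71935e-03	1.93463e-02	0.00000e+00
5.000e+01	9.77647e-04	1.87703e-02	0.00000e+00
6.000e+01	6.16387e-04	1.82392e-02	0.00000e+00
8.000e+01	2.97686e-04	1.72921e-02	0.00000e+00
1.000e+02	1.69269e-04	1.64718e-02	0.00000e+00
1.500e+02	6.06828e-05	1.48291e-02	0.00000e+00
2.000e+02	2.93069e-05	1.35881e-02	0.00000e+00
3.000e+02	1.05065e-05	1.18153e-02	0.00000e+00
4.000e+02	5.07417e-06	1.05861e-02	0.00000e+00
5.000e+02	2.88524e-06	9.66640e-03	0.00000e+00
6.000e+02	1.81909e-06	8.94203e-03	0.00000e+00
8.000e+02	8.78534e-07	7.85435e-03	0.00000e+00
1.000e+03	4.99547e-07	7.06037e-03	0.00000e+00
1.022e+03	4.72787e-07	6.98534e-03	0.00000e+00
1.100e+03	3.92512e-07	6.73502e-03	3.68213e-06
1.250e+03	2.84050e-07	6.31195e-03	1.07631e-05
1.500e+03	1.79088e-07	5.73554e-03	1.82791e-05
2.000e+03	8.64909e-08	4.89256e-03	4.93489e-05
3.000e+03	3.10070e-08	3.84733e-03	1.21639e-04
4.000e+03	1.49749e-08	3.20827e-03	1.94717e-04
5.000e+03	8.51495e-09	2.77007e-03	2.60925e-04
6.000e+03	5.36851e-09	2.44796e-03	3.22034e-04
7.000e+03	3.63478e-09	2.19976e-03	3.77238e-04
8.000e+03	2.59274e-09	2.00183e-03	4.27163e-04
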