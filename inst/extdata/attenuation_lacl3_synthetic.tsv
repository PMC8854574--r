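# synthetic photon attenuation table: lacl3
# density_g_cm3: 3.850
# columns: E_keV, mu_photo, mu_compton, mu_pair (linear coefficients, per mm)
# computed analytically (Klein-Nishina closed form; power-law photoelectric
# calibrated on lead anchors; pair production Z^2-scaled from standard water
# totals); coherent scattering omitted. See scripts/make_attenuation_tables.R
E_keV	mu_photo	mu_compton	mu_pair
1.000e+01	1.13003e+02	6.53884e-02	0.00000e+00
1.500e+01	4.05114e+01	6.42135e-02	0.00000e+00
2.000e+01	1.95651e+01	6.30930e-02	0.00000e+00
3.000e+01	7.01409e+00	6.10008e-02	0.00000e+00
4.000e+01	3.38748e+00	5.90859e-02	0.00000e+00
5.000e+01	1.92617e+00	5.73267e-02	0.00000e+00
6.000e+01	1.21441e+00	5.57047e-02	0.00000e+00
8.000e+01	5.86503e-01	5.28119e-02	0.00000e+00
1.000e+02	3.33494e-01	5.03068e-02	0.00000e+00
1.500e+02	1.19558e-01	4.52896e-02	0.00000e+00
2.000e+02	5.77407e-02	4.14996e-02	0.00000e+00
3.000e+02	2.07000e-02	3.60853e-02	0.00000e+00
4.000e+02	9.99715e-03	3.23312e-02	0.00000e+00
5.000e+02	5.68452e-03	2.95223e-02	0.00000e+00
6.000e+02	3.58398e-03	2.73100e-02	0.00000e+00
8.000e+02	1.73089e-03	2.39881e-02	0.00000e+00
1.000e+03	9.84211e-04	2.15631e-02	0.00000e+00
1.022e+03	9.31488e-04	2.13340e-02	0.00000e+00
1.100e+03	7.73330e-04	2.05695e-02	6.49369e-05
1.250e+03	5.59636e-04	1.92774e-02	1.89815e-04
1.500e+03	3.52840e-04	1.75170e-02	3.22365e-04
2.000e+03	1.70405e-04	1.49424e-02	8.70302e-04
3.000e+03	6.10902e-05	1.17502e-02	2.14518e-03
4.000e+03	2.95037e-05	9.79841e-03	3.43396e-03
5.000e+03	1.67762e-05	8.46009e-03	4.60159e-03
6.000e+03	1.05771e-05	7.47634e-03	5.67930e-03
7.000e+03	7.16127e-06	6.71831e-03	6.65286e-03
8.000e+03	5.10823e-06	6.11383e-03	7.53331e-03
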