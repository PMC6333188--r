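# Mass attenuation coefficients (total, with coherent scattering) for the
# elements of the tungsten-alloy MLC leaf material, transcribed in the style
# of the NIST XCOM database.  Units: energy_MeV in MeV, mu_rho_* in cm^2/g.
# The tungsten K-edge (69.5 keV) falls between the 0.06 and 0.08 MeV rows;
# log-log interpolation across that pair is inaccurate, so spectra used with
# this table should not extend below 0.08 MeV (package default cutoff 0.1).
energy_MeV	mu_rho_W	mu_rho_Ni	mu_rho_Fe
0.05	5.949	2.546	1.958
0.06	3.713	1.545	1.205
0.08	7.810	0.7306	0.5952
0.10	4.438	0.4440	0.3717
0.15	1.581	0.2208	0.1964
0.20	0.7844	0.1582	0.1460
0.30	0.3238	0.1154	0.1099
0.40	0.1925	0.09753	0.09400
0.50	0.1378	0.08672	0.08414
0.60	0.1093	0.07917	0.07704
0.80	0.08066	0.06874	0.06699
1.00	0.06618	0.06146	0.05995
1.25	0.05577	0.05483	0.05350
1.50	0.05000	0.05005	0.04883
2.00	0.04433	0.04377	0.04265
3.00	0.04075	0.03729	0.03621
4.00	0.04038	0.03426	0.03312
5.00	0.04103	0.03270	0.03146
6.00	0.04210	0.03193	0.03057
7.00	0.04336	0.03158	0.03014
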