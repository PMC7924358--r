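# Synthetic active-branch polarization curve (Butler-Volmer form,
# E0 = -0.5 V vs Ag/AgCl, i0 = 0.5 mA/cm^2, Tafel slopes 60/120 mV per decade).
# Not measured data: a stand-in trace for exercising tafel_extrapolate().
# E_V  i_mA_cm2
-0.90 -1077.22
-0.88 -733.9
-0.86 -500
-0.84 -340.646
-0.82 -232.079
-0.80 -158.114
-0.78 -107.722
-0.76 -73.3899
-0.74 -49.9999
-0.72 -34.0645
-0.70 -23.2077
-0.68 -15.8109
-0.66 -10.7711
-0.64 -7.33668
-0.62 -4.995
-0.60 -3.39569
-0.58 -2.29759
-0.56 -1.53114
-0.54 -0.969496
-0.52 -0.50182
-0.50 0
-0.48 0.736571
-0.46 2.08871
-0.44 4.84189
-0.42 10.6645
-0.40 23.1346
-0.38 49.95
-0.36 107.688
-0.34 232.056
-0.32 499.984
-0.30 1077.21
-0.28 2320.79
-0.26 4999.99
-0.24 10772.2
-0.22 23207.9
-0.20 50000
-0.18 107722
-0.16 232079
-0.14 500000
-0.12 1.07722e+06
-0.10 2.32079e+06
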