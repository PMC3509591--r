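# x U_kJmol
0.415 100.5548
0.42 84.90067
0.425 71.64673
0.43 60.52515
0.435 51.19241
0.44 43.08085
0.445 36.27102
0.45 30.41866
0.455 25.56676
0.46 21.28154
0.465 17.6747
0.47 14.59951
0.475 11.99193
0.48 9.805997
0.485 7.904856
0.49 6.341297
0.495 5.022261
0.5 3.951119
0.505 3.095592
0.51 2.374226
0.515 1.772218
0.52 1.367466
0.525 0.9387191
0.53 0.6746606
0.535 0.4593896
0.54 0.2770372
0.545 0.1893092
0.55 0.02769675
0.555 0.01223194
0.56 0
0.565 0.01454852
0.57 0.03800986
0.575 0.09631931
0.58 0.1554506
0.585 0.2358074
0.59 0.3106562
0.595 0.3903237
0.6 0.4282511
0.605 0.5582811
0.61 0.5947245
0.615 0.6990874
0.62 0.7647983
0.625 0.8879627
0.63 1.014781
0.635 1.081057
0.64 1.089283
0.645 1.336388
0.65 1.319065
0.655 1.436424
0.66 1.485981
0.665 1.587607
0.67 1.686291
0.675 1.796214
0.68 1.806754
0.685 1.906763
0.69 1.972314
0.695 1.992716
0.7 2.080492
0.705 2.113817
0.71 2.240918
0.715 2.295101
0.72 2.350704
0.725 2.313986
0.73 2.38316
0.735 2.503598
0.74 2.570559
0.745 2.551804
0.75 2.627551
0.755 2.69299
0.76 2.65008
0.765 2.726596
0.77 2.783017
0.775 2.814513
0.78 2.876028
0.785 2.876981
0.79 2.933935
0.795 2.899823
0.8 2.953127
0.805 3.028836
0.81 3.028399
0.815 3.033698
0.82 3.078854
0.825 3.161162
0.83 3.161403
0.835 3.116132
0.84 3.191169
0.845 3.191749
0.85 3.260189
0.855 3.282824
0.86 3.2314
0.865 3.352059
0.87 3.272228
0.875 3.340034
0.88 3.304213
0.885 3.339648
0.89 3.383182
0.895 3.33738
0.9 3.426401
0.905 3.445988
0.91 3.423486
0.915 3.42621
0.92 3.423862
0.925 3.496112
0.93 3.462091
0.935 3.454235
0.94 3.482672
0.945 3.480081
0.95 3.456135
0.955 3.57844
0.96 3.558461
0.965 3.535374
0.97 3.558899
0.975 3.490919
0.98 3.581036
0.985 3.568272
0.99 3.570687
0.995 3.576067
1 3.570745
1.005 3.609893
1.01 3.605072
1.015 3.586379
1.02 3.589395
1.025 3.606795
1.03 3.601362
1.035 3.628213
1.04 3.621011
1.045 3.678652
1.05 3.69013
1.055 3.70828
1.06 3.692733
1.065 3.649923
1.07 3.67885
1.075 3.66006
1.08 3.647827
1.085 3.742164
1.09 3.684282
1.095 3.680072
1.1 3.669085
1.105 3.712351
1.11 3.736025
1.115 3.711127
1.12 3.692784
1.125 3.738134
1.13 3.718915
1.135 3.75285
1.14 3.768672
1.145 3.700171
1.15 3.721266
1.155 3.665755
1.16 3.712972
1.165 3.738147
1.17 3.737054
1.175 3.769725
1.18 3.740889
1.185 3.695356
1.19 3.78331
1.195 3.73591
1.2 3.751921
1.205 3.730989
1.21 3.799718
1.215 3.780191
1.22 3.725419
1.225 3.74013
1.23 3.812328
1.235 3.770055
1.24 3.81331
1.245 3.782534
1.25 3.778607
1.255 3.690474
1.26 3.777689
1.265 3.708934
1.27 3.805642
1.275 3.794128
1.28 3.751179
1.285 3.771999
1.29 3.749846
1.295 3.800516
1.3 3.763601
1.305 3.793505
1.31 3.817142
1.315 3.737028
1.32 3.78638
1.325 3.790332
1.33 3.770883
1.335 3.810964
1.34 3.714394
1.345 3.759882
1.35 3.789035
1.355 3.746792
1.36 3.798822
1.365 3.766689
1.37 3.788857
1.375 3.788895
1.38 3.776311
1.385 3.796305
1.39 3.827837
1.395 3.780513
1.4 3.792338
1.405 3.825632
1.41 3.803545
1.415 3.825775
1.42 3.775665
1.425 3.782718
1.43 3.783218
1.435 3.770098
1.44 3.747865
1.445 3.840968
1.45 3.798451
1.455 3.783683
1.46 3.742456
1.465 3.831425
1.47 3.810608
1.475 3.849837
1.48 3.821088
1.485 3.788803
1.49 3.789996
1.495 3.79521
1.5 3.823359
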