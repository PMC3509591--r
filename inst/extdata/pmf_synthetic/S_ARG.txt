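# x U_kJmol
0.495 86.47205
0.5 75.0921
0.505 65.33143
0.51 56.80628
0.515 49.39017
0.52 42.93747
0.525 37.37191
0.53 32.40673
0.535 28.10083
0.54 24.34414
0.545 20.95447
0.55 17.98245
0.555 15.33705
0.56 13.14365
0.565 11.11894
0.57 9.363241
0.575 7.90591
0.58 6.666802
0.585 5.507846
0.59 4.577349
0.595 3.773133
0.6 3.083816
0.605 2.496933
0.61 1.966025
0.615 1.595603
0.62 1.24011
0.625 0.9825035
0.63 0.7117253
0.635 0.5504296
0.64 0.3791255
0.645 0.2603417
0.65 0.2382211
0.655 0.1238629
0.66 0.05359234
0.665 0.01474967
0.67 0.005400204
0.675 0.003802137
0.68 0
0.685 0.01575059
0.69 0.08322773
0.695 0.1314084
0.7 0.1649947
0.705 0.1531075
0.71 0.1875284
0.715 0.3214437
0.72 0.2936462
0.725 0.3969405
0.73 0.4662646
0.735 0.5487182
0.74 0.5879235
0.745 0.5732871
0.75 0.7211673
0.755 0.8122478
0.76 0.8242585
0.765 0.8669517
0.77 0.9320527
0.775 0.9630326
0.78 1.002714
0.785 1.073487
0.79 1.175744
0.795 1.174718
0.8 1.344891
0.805 1.332495
0.81 1.387091
0.815 1.433743
0.82 1.446717
0.825 1.496873
0.83 1.557361
0.835 1.579335
0.84 1.607118
0.845 1.692748
0.85 1.782611
0.855 1.755371
0.86 1.761321
0.865 1.801077
0.87 1.823386
0.875 1.873947
0.88 1.906706
0.885 1.943624
0.89 2.002168
0.895 2.040517
0.9 2.065267
0.905 2.123152
0.91 2.116494
0.915 2.133626
0.92 2.121175
0.925 2.209742
0.93 2.247222
0.935 2.188032
0.94 2.287713
0.945 2.287636
0.95 2.353084
0.955 2.32801
0.96 2.336107
0.965 2.412365
0.97 2.414318
0.975 2.365026
0.98 2.472509
0.985 2.438584
0.99 2.45268
0.995 2.450949
1 2.54454
1.005 2.482122
1.01 2.497987
1.015 2.508913
1.02 2.529045
1.025 2.618209
1.03 2.585754
1.035 2.584788
1.04 2.642267
1.045 2.535379
1.05 2.617613
1.055 2.618237
1.06 2.683946
1.065 2.652841
1.07 2.606154
1.075 2.665067
1.08 2.695639
1.085 2.692948
1.09 2.739654
1.095 2.733955
1.1 2.719058
1.105 2.739499
1.11 2.774513
1.115 2.780599
1.12 2.705569
1.125 2.727959
1.13 2.823919
1.135 2.75848
1.14 2.817387
1.145 2.784878
1.15 2.810927
1.155 2.765341
1.16 2.783016
1.165 2.815876
1.17 2.796624
1.175 2.817863
1.18 2.84722
1.185 2.844595
1.19 2.811291
1.195 2.842308
1.2 2.798818
1.205 2.812636
1.21 2.826115
1.215 2.861092
1.22 2.913998
1.225 2.878895
1.23 2.887668
1.235 2.852312
1.24 2.839395
1.245 2.867532
1.25 2.956249
1.255 2.832903
1.26 2.829444
1.265 2.899017
1.27 2.906051
1.275 2.899297
1.28 2.901147
1.285 2.844854
1.29 2.907007
1.295 2.883047
1.3 2.926258
1.305 2.910125
1.31 2.895085
1.315 2.883447
1.32 2.903984
1.325 2.862238
1.33 2.886594
1.335 2.919987
1.34 2.958564
1.345 2.950341
1.35 2.895722
1.355 2.916031
1.36 2.926133
1.365 2.933086
1.37 2.964663
1.375 3.02447
1.38 2.944534
1.385 2.982355
1.39 2.97583
1.395 2.890093
1.4 2.906653
1.405 2.966911
1.41 2.940834
1.415 2.923562
1.42 2.941954
1.425 2.944788
1.43 2.965255
1.435 2.979046
1.44 2.963478
1.445 2.970291
1.45 2.980593
1.455 2.894989
1.46 2.985344
1.465 2.879636
1.47 2.957391
1.475 2.968151
1.48 2.961739
1.485 2.978143
1.49 2.968023
1.495 2.976218
1.5 2.951991
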