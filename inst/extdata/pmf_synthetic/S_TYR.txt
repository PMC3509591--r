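# x U_kJmol
0.455 116.0907
0.46 99.53022
0.465 85.36507
0.47 73.17558
0.475 62.6879
0.48 53.74813
0.485 45.94278
0.49 39.23236
0.495 33.48392
0.5 28.39488
0.505 24.0907
0.51 20.28286
0.515 17.05886
0.52 14.28362
0.525 11.82904
0.53 9.794285
0.535 8.078418
0.54 6.619111
0.545 5.359707
0.55 4.30286
0.555 3.443104
0.56 2.681956
0.565 2.04942
0.57 1.623575
0.575 1.212601
0.58 0.8308233
0.585 0.6112364
0.59 0.4321067
0.595 0.24722
0.6 0.1177809
0.605 0.0351232
0.61 0.04932288
0.615 0.005633855
0.62 0
0.625 0.0009799444
0.63 0.01668667
0.635 0.06659583
0.64 0.1865205
0.645 0.1444721
0.65 0.2648373
0.655 0.3937732
0.66 0.4291468
0.665 0.4922407
0.67 0.5818135
0.675 0.685078
0.68 0.7963648
0.685 0.8939869
0.69 0.9723974
0.695 1.074054
0.7 1.160786
0.705 1.232843
0.71 1.333844
0.715 1.392427
0.72 1.505977
0.725 1.639403
0.73 1.653863
0.735 1.762646
0.74 1.822794
0.745 1.897219
0.75 1.930671
0.755 2.017961
0.76 2.097661
0.765 2.198225
0.77 2.28894
0.775 2.280267
0.78 2.383784
0.785 2.45512
0.79 2.512712
0.795 2.575806
0.8 2.584977
0.805 2.60164
0.81 2.722816
0.815 2.790928
0.82 2.784031
0.825 2.794288
0.83 2.88831
0.835 2.945591
0.84 2.997892
0.845 2.989867
0.85 3.034105
0.855 3.113046
0.86 3.099837
0.865 3.122032
0.87 3.238823
0.875 3.193004
0.88 3.259524
0.885 3.241918
0.89 3.288294
0.895 3.370237
0.9 3.361204
0.905 3.342291
0.91 3.393036
0.915 3.468516
0.92 3.477971
0.925 3.491004
0.93 3.522933
0.935 3.479627
0.94 3.590616
0.945 3.512573
0.95 3.553574
0.955 3.596007
0.96 3.608195
0.965 3.598694
0.97 3.647638
0.975 3.683463
0.98 3.691111
0.985 3.683921
0.99 3.707574
0.995 3.680571
1 3.689413
1.005 3.742008
1.01 3.771629
1.015 3.697457
1.02 3.817867
1.025 3.787315
1.03 3.811039
1.035 3.770163
1.04 3.829843
1.045 3.789864
1.05 3.879277
1.055 3.864773
1.06 3.851132
1.065 3.945656
1.07 3.882094
1.075 3.857573
1.08 3.866606
1.085 3.918974
1.09 3.877902
1.095 3.909865
1.1 3.952878
1.105 3.911678
1.11 3.874278
1.115 3.925343
1.12 3.93159
1.125 3.907899
1.13 3.981306
1.135 4.00233
1.14 3.974818
1.145 3.972841
1.15 4.014687
1.155 3.987862
1.16 4.033367
1.165 4.001169
1.17 3.990552
1.175 3.999533
1.18 4.012949
1.185 3.978574
1.19 3.997158
1.195 3.999208
1.2 3.993813
1.205 4.019189
1.21 4.053703
1.215 4.088276
1.22 4.084854
1.225 4.020621
1.23 3.995513
1.235 4.064659
1.24 4.060012
1.245 4.031702
1.25 4.063811
1.255 4.059603
1.26 4.070578
1.265 4.099831
1.27 4.065757
1.275 4.047659
1.28 4.088747
1.285 4.037874
1.29 4.082268
1.295 4.110538
1.3 4.11436
1.305 4.078643
1.31 4.142654
1.315 4.077418
1.32 4.099373
1.325 4.123262
1.33 4.126089
1.335 4.060092
1.34 4.132968
1.345 4.099992
1.35 4.112175
1.355 4.022654
1.36 4.090782
1.365 4.111724
1.37 4.114428
1.375 4.107437
1.38 4.096838
1.385 4.139072
1.39 4.136498
1.395 4.129816
1.4 4.12175
1.405 4.08023
1.41 4.148938
1.415 4.085651
1.42 4.141767
1.425 4.101617
1.43 4.091163
1.435 4.166964
1.44 4.159442
1.445 4.04535
1.45 4.117165
1.455 4.100323
1.46 4.102033
1.465 4.100292
1.47 4.091271
1.475 4.14648
1.48 4.169521
1.485 4.149711
1.49 4.119611
1.495 4.167938
1.5 4.14284
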