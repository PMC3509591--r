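# x U_kJmol
0.455 83.334
0.46 71.46508
0.465 61.36374
0.47 52.66825
0.475 45.25551
0.48 38.84602
0.485 33.28372
0.49 28.51456
0.495 24.35177
0.5 20.76308
0.505 17.61009
0.51 14.88484
0.515 12.52709
0.52 10.42017
0.525 8.674186
0.53 7.222057
0.535 5.946085
0.54 4.856074
0.545 3.914713
0.55 3.127877
0.555 2.512109
0.56 2.028355
0.565 1.541959
0.57 1.203355
0.575 0.9583731
0.58 0.7012516
0.585 0.4708892
0.59 0.3604769
0.595 0.2722111
0.6 0.1753559
0.605 0.1676877
0.61 0.1152245
0.615 0
0.62 0.07254574
0.625 0.09753082
0.63 0.07533002
0.635 0.1141796
0.64 0.19133
0.645 0.1508212
0.65 0.1820244
0.655 0.3642876
0.66 0.3387257
0.665 0.5080476
0.67 0.5230272
0.675 0.5753236
0.68 0.6045023
0.685 0.7341591
0.69 0.8173667
0.695 0.876805
0.7 0.8703209
0.705 0.9846717
0.71 1.037892
0.715 1.127233
0.72 1.150732
0.725 1.230647
0.73 1.269906
0.735 1.26749
0.74 1.351795
0.745 1.446995
0.75 1.499967
0.755 1.489997
0.76 1.611736
0.765 1.598182
0.77 1.69131
0.775 1.733037
0.78 1.775666
0.785 1.76772
0.79 1.844633
0.795 1.85593
0.8 1.998369
0.805 1.987646
0.81 1.984731
0.815 2.071585
0.82 2.120562
0.825 2.140471
0.83 2.173595
0.835 2.17789
0.84 2.183947
0.845 2.170938
0.85 2.269217
0.855 2.26087
0.86 2.297845
0.865 2.37386
0.87 2.339834
0.875 2.386934
0.88 2.373636
0.885 2.41039
0.89 2.422734
0.895 2.448597
0.9 2.433925
0.905 2.487524
0.91 2.503267
0.915 2.529151
0.92 2.566023
0.925 2.571273
0.93 2.59431
0.935 2.599809
0.94 2.621987
0.945 2.657048
0.95 2.57293
0.955 2.620919
0.96 2.646013
0.965 2.685981
0.97 2.683557
0.975 2.69642
0.98 2.703873
0.985 2.690975
0.99 2.641885
0.995 2.727848
1 2.772603
1.005 2.740895
1.01 2.746883
1.015 2.780664
1.02 2.758233
1.025 2.802387
1.03 2.766628
1.035 2.771324
1.04 2.838613
1.045 2.810232
1.05 2.835769
1.055 2.844397
1.06 2.824455
1.065 2.823008
1.07 2.841442
1.075 2.863919
1.08 2.869217
1.085 2.879233
1.09 2.871531
1.095 2.87865
1.1 2.890399
1.105 2.876195
1.11 2.884441
1.115 2.903988
1.12 2.91403
1.125 2.913221
1.13 2.90935
1.135 2.892987
1.14 2.905633
1.145 2.909836
1.15 2.954802
1.155 2.914101
1.16 2.955128
1.165 2.963422
1.17 2.934092
1.175 2.90647
1.18 2.971925
1.185 2.942365
1.19 2.904799
1.195 2.946035
1.2 2.974614
1.205 2.968609
1.21 2.955954
1.215 2.951484
1.22 2.957063
1.225 2.974351
1.23 2.990442
1.235 2.986117
1.24 2.954127
1.245 2.968056
1.25 2.951148
1.255 2.988577
1.26 2.978528
1.265 2.943596
1.27 2.966665
1.275 2.94193
1.28 2.992071
1.285 2.989559
1.29 3.009541
1.295 2.940207
1.3 3.00025
1.305 3.011492
1.31 2.95839
1.315 2.990184
1.32 2.987226
1.325 3.032764
1.33 2.985083
1.335 3.04483
1.34 3.019827
1.345 3.022398
1.35 2.99535
1.355 3.020631
1.36 2.973295
1.365 3.037704
1.37 3.019471
1.375 2.997048
1.38 3.039956
1.385 3.013573
1.39 3.060127
1.395 3.003147
1.4 3.023958
1.405 3.051991
1.41 2.979875
1.415 3.019017
1.42 3.042463
1.425 3.015361
1.43 2.985075
1.435 2.99508
1.44 3.068627
1.445 3.049508
1.45 3.01019
1.455 3.072036
1.46 3.002257
1.465 3.041468
1.47 2.950547
1.475 3.027904
1.48 2.96508
1.485 3.029767
1.49 3.047555
1.495 3.038017
1.5 3.030825
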