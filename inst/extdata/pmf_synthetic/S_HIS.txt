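# x U_kJmol
0.37 105.8089
0.375 87.64404
0.38 72.66806
0.385 60.20306
0.39 49.93282
0.395 41.34385
0.4 34.1921
0.405 28.13541
0.41 23.15401
0.415 18.86534
0.42 15.39915
0.425 12.44179
0.43 10.00807
0.435 7.979993
0.44 6.321635
0.445 4.88839
0.45 3.753524
0.455 2.832121
0.46 2.116352
0.465 1.498901
0.47 1.021234
0.475 0.7551139
0.48 0.4826031
0.485 0.3131565
0.49 0.2058949
0.495 0.0921172
0.5 0.002417798
0.505 0
0.51 0.00456923
0.515 0.05643858
0.52 0.09391643
0.525 0.1867181
0.53 0.258258
0.535 0.359827
0.54 0.4133403
0.545 0.4577891
0.55 0.5546218
0.555 0.6915812
0.56 0.7628948
0.565 0.8544285
0.57 0.9587174
0.575 1.048733
0.58 1.136465
0.585 1.230496
0.59 1.32473
0.595 1.35531
0.6 1.493719
0.605 1.584289
0.61 1.639492
0.615 1.694007
0.62 1.778904
0.625 1.852529
0.63 1.898821
0.635 1.900188
0.64 1.997105
0.645 2.101822
0.65 2.180444
0.655 2.229448
0.66 2.274282
0.665 2.266668
0.67 2.355403
0.675 2.423323
0.68 2.464323
0.685 2.500027
0.69 2.55247
0.695 2.569704
0.7 2.596755
0.705 2.60154
0.71 2.707366
0.715 2.716527
0.72 2.733114
0.725 2.774723
0.73 2.778455
0.735 2.821717
0.74 2.865766
0.745 2.842581
0.75 2.90206
0.755 2.943318
0.76 2.917823
0.765 2.956418
0.77 2.987569
0.775 3.01966
0.78 3.086427
0.785 3.060659
0.79 3.10821
0.795 3.017628
0.8 3.121456
0.805 3.186572
0.81 3.117327
0.815 3.188556
0.82 3.190991
0.825 3.17198
0.83 3.144013
0.835 3.226308
0.84 3.128928
0.845 3.204693
0.85 3.214399
0.855 3.280349
0.86 3.231441
0.865 3.224752
0.87 3.268233
0.875 3.244876
0.88 3.280585
0.885 3.277582
0.89 3.322478
0.895 3.281656
0.9 3.31933
0.905 3.318543
0.91 3.29705
0.915 3.332681
0.92 3.341234
0.925 3.361225
0.93 3.32219
0.935 3.315444
0.94 3.378697
0.945 3.298202
0.95 3.36566
0.955 3.414485
0.96 3.364016
0.965 3.41076
0.97 3.402076
0.975 3.351403
0.98 3.423878
0.985 3.359544
0.99 3.405375
0.995 3.416385
1 3.426713
1.005 3.398563
1.01 3.443832
1.015 3.429097
1.02 3.401655
1.025 3.451767
1.03 3.414769
1.035 3.478486
1.04 3.449595
1.045 3.434657
1.05 3.393216
1.055 3.508205
1.06 3.397206
1.065 3.429572
1.07 3.476702
1.075 3.473712
1.08 3.40595
1.085 3.475175
1.09 3.527645
1.095 3.486258
1.1 3.448583
1.105 3.423709
1.11 3.460608
1.115 3.452953
1.12 3.464238
1.125 3.454389
1.13 3.453985
1.135 3.420714
1.14 3.457512
1.145 3.466983
1.15 3.515628
1.155 3.460502
1.16 3.532585
1.165 3.506079
1.17 3.449495
1.175 3.451441
1.18 3.461942
1.185 3.514919
1.19 3.491707
1.195 3.436482
1.2 3.498395
1.205 3.468384
1.21 3.448383
1.215 3.482601
1.22 3.484289
1.225 3.505804
1.23 3.464019
1.235 3.4986
1.24 3.476117
1.245 3.461036
1.25 3.531881
1.255 3.497663
1.26 3.500741
1.265 3.47095
1.27 3.432378
1.275 3.501388
1.28 3.496758
1.285 3.500357
1.29 3.480114
1.295 3.540432
1.3 3.509576
1.305 3.471614
1.31 3.48547
1.315 3.44451
1.32 3.471679
1.325 3.480462
1.33 3.462534
1.335 3.535597
1.34 3.503548
1.345 3.484617
1.35 3.504168
1.355 3.518184
1.36 3.492325
1.365 3.547017
1.37 3.499671
1.375 3.530399
1.38 3.533813
1.385 3.507175
1.39 3.48372
1.395 3.485027
1.4 3.522771
1.405 3.514233
1.41 3.433165
1.415 3.513787
1.42 3.520054
1.425 3.524838
1.43 3.551839
1.435 3.492574
1.44 3.497433
1.445 3.54544
1.45 3.502763
1.455 3.441497
1.46 3.47415
1.465 3.521574
1.47 3.498182
1.475 3.502129
1.48 3.500878
1.485 3.565333
1.49 3.480136
1.495 3.544932
1.5 3.503304
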