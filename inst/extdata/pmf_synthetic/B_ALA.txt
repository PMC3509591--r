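# x U_kJmol
0.415 84.82313
0.42 71.68547
0.425 60.57912
0.43 51.17539
0.435 43.21804
0.44 36.46386
0.445 30.79096
0.45 25.91208
0.455 21.61398
0.46 18.09345
0.465 15.07867
0.47 12.43165
0.475 10.18523
0.48 8.356578
0.485 6.7138
0.49 5.388154
0.495 4.254265
0.5 3.392885
0.505 2.678568
0.51 2.056552
0.515 1.479683
0.52 1.093987
0.525 0.7688287
0.53 0.5457092
0.535 0.4922493
0.54 0.2528079
0.545 0.1663098
0.55 0.1007913
0.555 0.01685599
0.56 0.03557567
0.565 0.06048946
0.57 0
0.575 0.1853802
0.58 0.1393407
0.585 0.1423924
0.59 0.2000625
0.595 0.2810624
0.6 0.3823682
0.605 0.4544668
0.61 0.5192069
0.615 0.6472125
0.62 0.6626129
0.625 0.7341368
0.63 0.8932728
0.635 0.9183087
0.64 1.020645
0.645 1.084783
0.65 1.134754
0.655 1.158202
0.66 1.231893
0.665 1.306291
0.67 1.340565
0.675 1.417464
0.68 1.538005
0.685 1.571371
0.69 1.683288
0.695 1.626683
0.7 1.77251
0.705 1.843649
0.71 1.807317
0.715 1.90361
0.72 1.88359
0.725 1.995532
0.73 1.997558
0.735 2.105429
0.74 2.199082
0.745 2.227451
0.75 2.208901
0.755 2.271856
0.76 2.247879
0.765 2.302195
0.77 2.275943
0.775 2.334404
0.78 2.388774
0.785 2.45776
0.79 2.437885
0.795 2.475286
0.8 2.503734
0.805 2.549107
0.81 2.530728
0.815 2.571134
0.82 2.639441
0.825 2.614021
0.83 2.635185
0.835 2.687156
0.84 2.696626
0.845 2.694386
0.85 2.785377
0.855 2.714067
0.86 2.756597
0.865 2.804072
0.87 2.802077
0.875 2.769125
0.88 2.823007
0.885 2.799013
0.89 2.864626
0.895 2.851583
0.9 2.863291
0.905 2.910844
0.91 2.877836
0.915 2.820749
0.92 2.879676
0.925 2.935863
0.93 2.9098
0.935 2.876027
0.94 3.007968
0.945 2.982399
0.95 2.9327
0.955 2.921078
0.96 2.96637
0.965 2.984996
0.97 3.015384
0.975 3.057641
0.98 3.010605
0.985 2.975934
0.99 3.064923
0.995 3.035287
1 3.043826
1.005 3.013658
1.01 3.035207
1.015 3.105579
1.02 3.038362
1.025 3.039258
1.03 3.071728
1.035 3.049966
1.04 3.116534
1.045 3.064653
1.05 3.13162
1.055 3.09424
1.06 3.132207
1.065 3.111006
1.07 3.117369
1.075 3.115354
1.08 3.098344
1.085 3.081503
1.09 3.144234
1.095 3.08043
1.1 3.066526
1.105 3.065895
1.11 3.178649
1.115 3.123361
1.12 3.142402
1.125 3.095819
1.13 3.174833
1.135 3.161849
1.14 3.093736
1.145 3.139631
1.15 3.155308
1.155 3.147226
1.16 3.14743
1.165 3.160031
1.17 3.14393
1.175 3.186392
1.18 3.1413
1.185 3.149644
1.19 3.227936
1.195 3.227586
1.2 3.218134
1.205 3.212383
1.21 3.123454
1.215 3.132759
1.22 3.135958
1.225 3.143108
1.23 3.143456
1.235 3.16919
1.24 3.122545
1.245 3.154074
1.25 3.108702
1.255 3.175671
1.26 3.187473
1.265 3.215107
1.27 3.126229
1.275 3.246401
1.28 3.160379
1.285 3.232912
1.29 3.23365
1.295 3.09965
1.3 3.212788
1.305 3.197981
1.31 3.126853
1.315 3.151607
1.32 3.200744
1.325 3.178217
1.33 3.180111
1.335 3.229481
1.34 3.192576
1.345 3.186555
1.35 3.201999
1.355 3.193747
1.36 3.208311
1.365 3.188251
1.37 3.213614
1.375 3.194366
1.38 3.161678
1.385 3.199924
1.39 3.173474
1.395 3.197482
1.4 3.197007
1.405 3.20141
1.41 3.21309
1.415 3.214941
1.42 3.200296
1.425 3.162111
1.43 3.225864
1.435 3.183084
1.44 3.217435
1.445 3.198603
1.45 3.185687
1.455 3.147129
1.46 3.225539
1.465 3.247903
1.47 3.253586
1.475 3.175015
1.48 3.238738
1.485 3.228882
1.49 3.275819
1.495 3.227233
1.5 3.232423
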