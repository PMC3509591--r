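# x U_kJmol
0.535 106.9168
0.54 93.84462
0.545 82.44715
0.55 72.42444
0.555 63.58584
0.56 55.91266
0.565 49.0582
0.57 43.06475
0.575 37.77866
0.58 33.03718
0.585 28.89923
0.59 25.12243
0.595 21.81212
0.6 18.91001
0.605 16.32308
0.61 13.99659
0.615 12.05239
0.62 10.20887
0.625 8.637311
0.63 7.386992
0.635 6.285914
0.64 5.270155
0.645 4.365013
0.65 3.673681
0.655 3.034714
0.66 2.492302
0.665 2.010055
0.67 1.597034
0.675 1.284657
0.68 1.036721
0.685 0.8001319
0.69 0.5613417
0.695 0.476327
0.7 0.333383
0.705 0.2562975
0.71 0.1733039
0.715 0.112332
0.72 0
0.725 0.07149053
0.73 0.01915683
0.735 0.07024627
0.74 0.07248137
0.745 0.05172518
0.75 0.1596706
0.755 0.1427492
0.76 0.1957513
0.765 0.2693557
0.77 0.3883773
0.775 0.3439873
0.78 0.4610858
0.785 0.5131611
0.79 0.5437075
0.795 0.5606977
0.8 0.6734141
0.805 0.761649
0.81 0.8105235
0.815 0.9136511
0.82 0.9249866
0.825 1.028899
0.83 1.09555
0.835 1.126463
0.84 1.230542
0.845 1.278013
0.85 1.329688
0.855 1.431875
0.86 1.430393
0.865 1.475834
0.87 1.545807
0.875 1.557597
0.88 1.683837
0.885 1.729171
0.89 1.76728
0.895 1.819026
0.9 1.834067
0.905 1.978758
0.91 1.94552
0.915 2.022928
0.92 2.070901
0.925 2.085656
0.93 2.117964
0.935 2.214935
0.94 2.255121
0.945 2.260466
0.95 2.334145
0.955 2.350978
0.96 2.365027
0.965 2.436903
0.97 2.432172
0.975 2.49661
0.98 2.537104
0.985 2.585349
0.99 2.589337
0.995 2.539785
1 2.604608
1.005 2.688763
1.01 2.652451
1.015 2.700072
1.02 2.769746
1.025 2.730744
1.03 2.799839
1.035 2.820569
1.04 2.771921
1.045 2.864837
1.05 2.859674
1.055 2.88712
1.06 2.967582
1.065 2.910594
1.07 2.944763
1.075 3.023777
1.08 2.990133
1.085 3.003148
1.09 3.000638
1.095 3.053549
1.1 3.030553
1.105 3.063802
1.11 3.121425
1.115 3.076484
1.12 3.101028
1.125 3.081934
1.13 3.152321
1.135 3.177429
1.14 3.125688
1.145 3.157053
1.15 3.228026
1.155 3.241925
1.16 3.256379
1.165 3.230898
1.17 3.241502
1.175 3.224706
1.18 3.25318
1.185 3.304744
1.19 3.26116
1.195 3.27575
1.2 3.304075
1.205 3.3164
1.21 3.287083
1.215 3.29171
1.22 3.339138
1.225 3.323121
1.23 3.368781
1.235 3.337347
1.24 3.313888
1.245 3.352229
1.25 3.378923
1.255 3.340044
1.26 3.348621
1.265 3.379543
1.27 3.370324
1.275 3.332962
1.28 3.429968
1.285 3.358245
1.29 3.383114
1.295 3.430494
1.3 3.43086
1.305 3.388492
1.31 3.426027
1.315 3.436981
1.32 3.419512
1.325 3.426042
1.33 3.404922
1.335 3.404846
1.34 3.457346
1.345 3.468666
1.35 3.451455
1.355 3.52804
1.36 3.470579
1.365 3.544515
1.37 3.434566
1.375 3.432711
1.38 3.503424
1.385 3.517
1.39 3.491796
1.395 3.498262
1.4 3.526534
1.405 3.51234
1.41 3.48487
1.415 3.490666
1.42 3.513897
1.425 3.494876
1.43 3.495633
1.435 3.514432
1.44 3.558756
1.445 3.497421
1.45 3.563194
1.455 3.584927
1.46 3.551595
1.465 3.490985
1.47 3.519718
1.475 3.519375
1.48 3.557677
1.485 3.559987
1.49 3.554037
1.495 3.502041
1.5 3.524736
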