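# x U_kJmol
0.415 118.8486
0.42 100.2988
0.425 84.6023
0.43 71.39053
0.435 60.23222
0.44 50.6988
0.445 42.63462
0.45 35.7677
0.455 29.96082
0.46 24.94195
0.465 20.73273
0.47 17.08069
0.475 14.0369
0.48 11.45654
0.485 9.247485
0.49 7.463367
0.495 5.928033
0.5 4.671188
0.505 3.638835
0.51 2.797433
0.515 2.054636
0.52 1.578595
0.525 1.075664
0.53 0.720482
0.535 0.5034063
0.54 0.3561559
0.545 0.195771
0.55 0
0.555 0.02070261
0.56 0.01879005
0.565 0.04456994
0.57 0.07038502
0.575 0.06441031
0.58 0.1765811
0.585 0.2153461
0.59 0.3333153
0.595 0.4008897
0.6 0.4815445
0.605 0.6108676
0.61 0.721994
0.615 0.8100985
0.62 0.856819
0.625 0.9858054
0.63 1.113065
0.635 1.235722
0.64 1.329136
0.645 1.450228
0.65 1.583844
0.655 1.632705
0.66 1.754734
0.665 1.802728
0.67 1.878144
0.675 1.98352
0.68 2.108203
0.685 2.20016
0.69 2.226206
0.695 2.370587
0.7 2.401886
0.705 2.510903
0.71 2.569212
0.715 2.596766
0.72 2.709141
0.725 2.778121
0.73 2.821829
0.735 2.892822
0.74 2.955139
0.745 2.995781
0.75 3.100718
0.755 3.170796
0.76 3.192428
0.765 3.2273
0.77 3.257289
0.775 3.314394
0.78 3.377395
0.785 3.352069
0.79 3.439123
0.795 3.511676
0.8 3.489014
0.805 3.538675
0.81 3.542523
0.815 3.624666
0.82 3.632312
0.825 3.653004
0.83 3.698958
0.835 3.730214
0.84 3.677265
0.845 3.751173
0.85 3.802451
0.855 3.83969
0.86 3.807504
0.865 3.84221
0.87 3.944977
0.875 3.87957
0.88 3.862106
0.885 3.916111
0.89 3.954339
0.895 3.993498
0.9 4.028327
0.905 4.01204
0.91 3.962222
0.915 3.98698
0.92 4.079493
0.925 4.051605
0.93 4.062202
0.935 4.12148
0.94 4.116901
0.945 4.105872
0.95 4.110235
0.955 4.145281
0.96 4.172446
0.965 4.191138
0.97 4.204458
0.975 4.152781
0.98 4.191932
0.985 4.246331
0.99 4.252929
0.995 4.204555
1 4.19604
1.005 4.225597
1.01 4.252012
1.015 4.26102
1.02 4.292759
1.025 4.260799
1.03 4.297156
1.035 4.258886
1.04 4.301149
1.045 4.331396
1.05 4.272541
1.055 4.33718
1.06 4.362868
1.065 4.330596
1.07 4.284431
1.075 4.274944
1.08 4.381384
1.085 4.329121
1.09 4.299649
1.095 4.380441
1.1 4.305526
1.105 4.37434
1.11 4.344625
1.115 4.351901
1.12 4.380847
1.125 4.339604
1.13 4.349705
1.135 4.400317
1.14 4.360561
1.145 4.421246
1.15 4.38589
1.155 4.364304
1.16 4.36905
1.165 4.431638
1.17 4.439192
1.175 4.391926
1.18 4.404813
1.185 4.387537
1.19 4.412298
1.195 4.472188
1.2 4.402258
1.205 4.405408
1.21 4.386009
1.215 4.371276
1.22 4.388829
1.225 4.396127
1.23 4.37739
1.235 4.483841
1.24 4.440022
1.245 4.399547
1.25 4.397518
1.255 4.401148
1.26 4.42019
1.265 4.382301
1.27 4.44211
1.275 4.440904
1.28 4.410687
1.285 4.461218
1.29 4.402339
1.295 4.453885
1.3 4.381564
1.305 4.415558
1.31 4.442399
1.315 4.463879
1.32 4.484163
1.325 4.472878
1.33 4.399006
1.335 4.459224
1.34 4.464145
1.345 4.449313
1.35 4.425258
1.355 4.46722
1.36 4.445576
1.365 4.418136
1.37 4.421197
1.375 4.434162
1.38 4.510528
1.385 4.448405
1.39 4.455916
1.395 4.484413
1.4 4.467167
1.405 4.46411
1.41 4.450857
1.415 4.461195
1.42 4.414676
1.425 4.44879
1.43 4.465976
1.435 4.463888
1.44 4.447677
1.445 4.488178
1.45 4.443431
1.455 4.497355
1.46 4.48991
1.465 4.422085
1.47 4.494661
1.475 4.468191
1.48 4.506445
1.485 4.511302
1.49 4.459603
1.495 4.470412
1.5 4.4898
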