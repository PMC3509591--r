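# x U_kJmol
0.37 90.81368
0.375 75.302
0.38 62.46837
0.385 51.80362
0.39 43.01775
0.395 35.61944
0.4 29.48285
0.405 24.36699
0.41 20.05605
0.415 16.44343
0.42 13.40755
0.425 10.87664
0.43 8.715699
0.435 6.911125
0.44 5.444242
0.445 4.230632
0.45 3.257839
0.455 2.473753
0.46 1.813949
0.465 1.332925
0.47 0.9163302
0.475 0.6581121
0.48 0.4038064
0.485 0.2378843
0.49 0.09700461
0.495 0.04775202
0.5 0.04632494
0.505 0.005290028
0.51 0
0.515 0.06849607
0.52 0.08240589
0.525 0.1846859
0.53 0.1859141
0.535 0.2891803
0.54 0.3409183
0.545 0.3844669
0.55 0.5628594
0.555 0.5577965
0.56 0.6309449
0.565 0.7160755
0.57 0.7806166
0.575 0.8526993
0.58 0.9105848
0.585 0.9865192
0.59 1.105622
0.595 1.204916
0.6 1.279452
0.605 1.365471
0.61 1.397985
0.615 1.445562
0.62 1.508508
0.625 1.555355
0.63 1.583487
0.635 1.637689
0.64 1.749169
0.645 1.764469
0.65 1.829081
0.655 1.932368
0.66 1.932737
0.665 1.939846
0.67 2.015328
0.675 2.058051
0.68 2.096074
0.685 2.132222
0.69 2.134107
0.695 2.154758
0.7 2.17525
0.705 2.28864
0.71 2.291384
0.715 2.283433
0.72 2.31779
0.725 2.352193
0.73 2.392556
0.735 2.417166
0.74 2.468262
0.745 2.451831
0.75 2.466531
0.755 2.484537
0.76 2.519568
0.765 2.525972
0.77 2.527408
0.775 2.570428
0.78 2.62322
0.785 2.609607
0.79 2.614356
0.795 2.668297
0.8 2.637782
0.805 2.696454
0.81 2.631336
0.815 2.694806
0.82 2.727166
0.825 2.711307
0.83 2.695782
0.835 2.748828
0.84 2.744217
0.845 2.800205
0.85 2.773034
0.855 2.756936
0.86 2.808528
0.865 2.797977
0.87 2.819252
0.875 2.835187
0.88 2.816882
0.885 2.769474
0.89 2.814602
0.895 2.815624
0.9 2.847626
0.905 2.835243
0.91 2.868997
0.915 2.81497
0.92 2.849508
0.925 2.883213
0.93 2.871279
0.935 2.893174
0.94 2.82293
0.945 2.846305
0.95 2.867469
0.955 2.874913
0.96 2.876423
0.965 2.854896
0.97 2.87259
0.975 2.881391
0.98 2.931894
0.985 2.886752
0.99 2.90357
0.995 2.918379
1 2.879535
1.005 2.944376
1.01 2.885371
1.015 2.892631
1.02 2.913912
1.025 2.961481
1.03 2.889824
1.035 2.874837
1.04 2.921246
1.045 2.917316
1.05 2.936813
1.055 2.985068
1.06 2.972897
1.065 2.880385
1.07 2.933213
1.075 2.94386
1.08 2.961094
1.085 2.96994
1.09 2.989659
1.095 2.957206
1.1 2.924426
1.105 2.935667
1.11 2.932886
1.115 2.930846
1.12 2.975038
1.125 2.90041
1.13 3.005337
1.135 2.902149
1.14 2.945797
1.145 2.956086
1.15 2.987069
1.155 3.044683
1.16 3.016228
1.165 2.98613
1.17 2.991626
1.175 3.015766
1.18 2.965123
1.185 2.975454
1.19 2.961083
1.195 2.997809
1.2 2.989905
1.205 2.955753
1.21 3.024292
1.215 2.972606
1.22 3.005375
1.225 2.956913
1.23 2.922434
1.235 2.968387
1.24 2.923847
1.245 2.953294
1.25 2.918172
1.255 3.013806
1.26 2.993504
1.265 2.987784
1.27 2.940141
1.275 2.990243
1.28 2.979858
1.285 2.940404
1.29 2.970103
1.295 3.03318
1.3 3.02454
1.305 2.988241
1.31 2.996503
1.315 2.942717
1.32 3.019742
1.325 2.97855
1.33 2.989296
1.335 2.987339
1.34 2.977223
1.345 2.985294
1.35 3.027335
1.355 2.982785
1.36 2.993033
1.365 3.008889
1.37 2.987227
1.375 2.989762
1.38 3.007068
1.385 2.970157
1.39 2.955176
1.395 3.046346
1.4 3.040008
1.405 2.966999
1.41 3.000566
1.415 3.060504
1.42 2.995122
1.425 3.04386
1.43 2.971287
1.435 3.015604
1.44 2.929016
1.445 3.018701
1.45 2.95954
1.455 3.018822
1.46 3.01506
1.465 2.964724
1.47 2.978245
1.475 3.002805
1.48 3.003712
1.485 3.046354
1.49 2.976213
1.495 2.998681
1.5 2.984249
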