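# x U_kJmol
0.415 79.6774
0.42 67.24712
0.425 56.92717
0.43 48.16636
0.435 40.64159
0.44 34.33716
0.445 28.94962
0.45 24.35712
0.455 20.39887
0.46 17.08137
0.465 14.13631
0.47 11.71575
0.475 9.606796
0.48 7.83694
0.485 6.430871
0.49 5.166731
0.495 4.061799
0.5 3.215994
0.505 2.441195
0.51 1.928216
0.515 1.46122
0.52 1.05296
0.525 0.7988938
0.53 0.5059212
0.535 0.4002374
0.54 0.2410996
0.545 0.1471858
0.55 0.04714798
0.555 0
0.56 0.02362827
0.565 0.003545173
0.57 0.06457554
0.575 0.1141542
0.58 0.1071695
0.585 0.2137265
0.59 0.2711719
0.595 0.2956924
0.6 0.352277
0.605 0.4293594
0.61 0.5286682
0.615 0.5154714
0.62 0.6791808
0.625 0.691681
0.63 0.797514
0.635 0.8703342
0.64 0.8972821
0.645 0.9609237
0.65 1.077416
0.655 1.169704
0.66 1.243182
0.665 1.260467
0.67 1.351415
0.675 1.405728
0.68 1.451803
0.685 1.434879
0.69 1.537613
0.695 1.620481
0.7 1.677559
0.705 1.678373
0.71 1.749518
0.715 1.792842
0.72 1.79138
0.725 1.88612
0.73 1.921558
0.735 1.99862
0.74 2.040922
0.745 2.064628
0.75 2.067949
0.755 2.111523
0.76 2.098807
0.765 2.204545
0.77 2.224512
0.775 2.255979
0.78 2.281014
0.785 2.281826
0.79 2.371988
0.795 2.337254
0.8 2.400263
0.805 2.406547
0.81 2.414849
0.815 2.450111
0.82 2.393304
0.825 2.443573
0.83 2.499704
0.835 2.463155
0.84 2.543146
0.845 2.503618
0.85 2.543154
0.855 2.628901
0.86 2.595892
0.865 2.638646
0.87 2.61155
0.875 2.631284
0.88 2.651776
0.885 2.617408
0.89 2.671321
0.895 2.704929
0.9 2.725927
0.905 2.703193
0.91 2.724673
0.915 2.744137
0.92 2.756378
0.925 2.750618
0.93 2.783973
0.935 2.741322
0.94 2.75295
0.945 2.761309
0.95 2.778463
0.955 2.816923
0.96 2.832088
0.965 2.776803
0.97 2.85504
0.975 2.766689
0.98 2.834634
0.985 2.860981
0.99 2.843438
0.995 2.834654
1 2.817192
1.005 2.858184
1.01 2.840111
1.015 2.896961
1.02 2.861024
1.025 2.83686
1.03 2.860223
1.035 2.859879
1.04 2.90071
1.045 2.898883
1.05 2.903681
1.055 2.884006
1.06 2.955183
1.065 2.887658
1.07 2.920014
1.075 2.900372
1.08 2.863063
1.085 2.916225
1.09 2.88005
1.095 2.936211
1.1 2.974979
1.105 2.964616
1.11 2.96782
1.115 2.942289
1.12 2.966633
1.125 2.903811
1.13 2.964323
1.135 2.99643
1.14 2.937208
1.145 2.937429
1.15 2.92834
1.155 2.95896
1.16 2.968317
1.165 2.995796
1.17 3.029769
1.175 2.984968
1.18 3.011811
1.185 2.939267
1.19 2.98156
1.195 3.026011
1.2 2.936521
1.205 2.969798
1.21 2.951206
1.215 2.937602
1.22 2.949382
1.225 2.971094
1.23 3.033951
1.235 3.018042
1.24 2.995653
1.245 2.988774
1.25 2.965294
1.255 2.911343
1.26 2.969614
1.265 2.997256
1.27 2.986063
1.275 3.003052
1.28 3.017903
1.285 3.060257
1.29 2.999896
1.295 3.039849
1.3 3.012084
1.305 3.006933
1.31 3.022115
1.315 3.044956
1.32 3.046738
1.325 3.047098
1.33 2.971409
1.335 2.962288
1.34 2.996731
1.345 2.99081
1.35 3.023504
1.355 3.000863
1.36 3.001619
1.365 2.951964
1.37 3.037952
1.375 2.989132
1.38 3.009008
1.385 3.06428
1.39 3.032701
1.395 2.999592
1.4 2.978943
1.405 3.010425
1.41 3.04722
1.415 3.013584
1.42 3.010845
1.425 2.995812
1.43 2.98896
1.435 3.030033
1.44 3.042791
1.445 3.027119
1.45 2.937841
1.455 3.055936
1.46 3.007712
1.465 3.016015
1.47 3.076824
1.475 2.959055
1.48 3.007985
1.485 3.018578
1.49 3.030637
1.495 3.034379
1.5 2.989485
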