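# x U_kJmol
0.535 148.1783
0.54 129.9961
0.545 114.04
0.55 100.0747
0.555 87.8466
0.56 77.09539
0.565 67.60721
0.57 59.20975
0.575 51.82637
0.58 45.29568
0.585 39.52556
0.59 34.35898
0.595 29.84474
0.6 25.8399
0.605 22.2655
0.61 19.1817
0.615 16.46218
0.62 14.0469
0.625 11.98562
0.63 10.15447
0.635 8.577505
0.64 7.201628
0.645 6.048435
0.65 4.983566
0.655 4.169142
0.66 3.417042
0.665 2.815738
0.67 2.162948
0.675 1.795436
0.68 1.39004
0.685 1.048197
0.69 0.7765149
0.695 0.5482155
0.7 0.4543228
0.705 0.2398641
0.71 0.1510067
0.715 0.1147537
0.72 0.03742709
0.725 0.02857896
0.73 0.03321254
0.735 0
0.74 0.05178097
0.745 0.08548863
0.75 0.1366196
0.755 0.1825422
0.76 0.2455118
0.765 0.3312295
0.77 0.4122394
0.775 0.5003745
0.78 0.5422944
0.785 0.6000179
0.79 0.7383942
0.795 0.8403075
0.8 0.9395738
0.805 1.010761
0.81 1.061418
0.815 1.152544
0.82 1.267304
0.825 1.428785
0.83 1.432146
0.835 1.595905
0.84 1.551286
0.845 1.714224
0.85 1.820342
0.855 1.8732
0.86 1.978891
0.865 2.040913
0.87 2.172239
0.875 2.168633
0.88 2.286684
0.885 2.348124
0.89 2.369397
0.895 2.487586
0.9 2.584248
0.905 2.646559
0.91 2.699655
0.915 2.773861
0.92 2.79323
0.925 2.879208
0.93 2.93235
0.935 3.00016
0.94 3.017202
0.945 3.127679
0.95 3.11573
0.955 3.258874
0.96 3.293205
0.965 3.327802
0.97 3.310131
0.975 3.376312
0.98 3.41168
0.985 3.458933
0.99 3.550711
0.995 3.556804
1 3.584634
1.005 3.699446
1.01 3.672231
1.015 3.76708
1.02 3.728659
1.025 3.82374
1.03 3.805924
1.035 3.845769
1.04 3.855672
1.045 3.899402
1.05 3.986025
1.055 3.949066
1.06 3.979469
1.065 4.050609
1.07 4.033687
1.075 4.088468
1.08 4.083762
1.085 4.138337
1.09 4.140238
1.095 4.19054
1.1 4.206925
1.105 4.271513
1.11 4.225997
1.115 4.258156
1.12 4.34763
1.125 4.264429
1.13 4.29318
1.135 4.262688
1.14 4.363356
1.145 4.335196
1.15 4.371183
1.155 4.404885
1.16 4.376994
1.165 4.391285
1.17 4.442841
1.175 4.448471
1.18 4.463056
1.185 4.473419
1.19 4.463115
1.195 4.494724
1.2 4.514749
1.205 4.520795
1.21 4.549679
1.215 4.551186
1.22 4.569981
1.225 4.5574
1.23 4.576971
1.235 4.583084
1.24 4.601669
1.245 4.654688
1.25 4.596552
1.255 4.714519
1.26 4.631125
1.265 4.665583
1.27 4.620558
1.275 4.662167
1.28 4.676835
1.285 4.653808
1.29 4.70792
1.295 4.691917
1.3 4.689244
1.305 4.710984
1.31 4.747725
1.315 4.781318
1.32 4.691641
1.325 4.685259
1.33 4.718647
1.335 4.72336
1.34 4.69355
1.345 4.72884
1.35 4.728441
1.355 4.740265
1.36 4.766049
1.365 4.791789
1.37 4.733278
1.375 4.777555
1.38 4.762239
1.385 4.784487
1.39 4.777431
1.395 4.747873
1.4 4.895682
1.405 4.792144
1.41 4.827657
1.415 4.767423
1.42 4.772393
1.425 4.817917
1.43 4.826526
1.435 4.857193
1.44 4.804824
1.445 4.798172
1.45 4.792321
1.455 4.877082
1.46 4.861936
1.465 4.870899
1.47 4.915674
1.475 4.843181
1.48 4.870358
1.485 4.91099
1.49 4.870347
1.495 4.885339
1.5 4.914916
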