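# x U_kJmol
0.37 96.85583
0.375 80.18452
0.38 66.52803
0.385 55.11059
0.39 45.70615
0.395 37.85837
0.4 31.3211
0.405 25.88331
0.41 21.25753
0.415 17.3722
0.42 14.06633
0.425 11.45926
0.43 9.19198
0.435 7.287001
0.44 5.706867
0.445 4.434143
0.45 3.470362
0.455 2.619687
0.46 1.917656
0.465 1.329492
0.47 0.9379062
0.475 0.5870102
0.48 0.3749143
0.485 0.2117803
0.49 0.122132
0.495 0.09160995
0.5 0.0009602751
0.505 0.02103413
0.51 0
0.515 0.03638874
0.52 0.06645305
0.525 0.1016693
0.53 0.1615315
0.535 0.2938028
0.54 0.3685821
0.545 0.4017973
0.55 0.4685408
0.555 0.5572115
0.56 0.7181248
0.565 0.6966109
0.57 0.8009137
0.575 0.9218599
0.58 0.9228412
0.585 1.041316
0.59 1.147367
0.595 1.192701
0.6 1.306377
0.605 1.286805
0.61 1.439975
0.615 1.477965
0.62 1.560881
0.625 1.679203
0.63 1.718456
0.635 1.758468
0.64 1.810695
0.645 1.886641
0.65 1.917194
0.655 1.980079
0.66 1.973446
0.665 2.061709
0.67 2.122914
0.675 2.114891
0.68 2.215248
0.685 2.223776
0.69 2.243095
0.695 2.284985
0.7 2.348895
0.705 2.323606
0.71 2.41087
0.715 2.442746
0.72 2.374918
0.725 2.477506
0.73 2.489535
0.735 2.548484
0.74 2.524714
0.745 2.590518
0.75 2.595855
0.755 2.627892
0.76 2.666996
0.765 2.655937
0.77 2.630102
0.775 2.716317
0.78 2.682813
0.785 2.749008
0.79 2.749394
0.795 2.749567
0.8 2.842329
0.805 2.753688
0.81 2.814248
0.815 2.794583
0.82 2.8916
0.825 2.784624
0.83 2.827971
0.835 2.861912
0.84 2.863086
0.845 2.903722
0.85 2.851699
0.855 2.888332
0.86 2.955546
0.865 2.908693
0.87 2.937629
0.875 2.905257
0.88 3.002857
0.885 2.953504
0.89 2.943463
0.895 2.960061
0.9 2.906658
0.905 3.000993
0.91 2.953576
0.915 2.956782
0.92 3.024855
0.925 2.998063
0.93 2.972635
0.935 2.983566
0.94 3.028256
0.945 3.009506
0.95 3.038044
0.955 3.012715
0.96 3.057755
0.965 3.026702
0.97 3.076102
0.975 3.074499
0.98 3.082859
0.985 3.009978
0.99 3.041781
0.995 3.048705
1 3.128361
1.005 3.052005
1.01 3.071134
1.015 3.068369
1.02 3.127417
1.025 3.122582
1.03 3.05678
1.035 3.127588
1.04 3.095596
1.045 3.069994
1.05 3.061178
1.055 3.07397
1.06 3.105616
1.065 3.085194
1.07 3.074471
1.075 3.081407
1.08 3.041131
1.085 3.122575
1.09 3.135629
1.095 3.067409
1.1 3.073312
1.105 3.053355
1.11 3.110374
1.115 3.119115
1.12 3.074698
1.125 3.150568
1.13 3.085558
1.135 3.11286
1.14 3.123112
1.145 3.085409
1.15 3.150734
1.155 3.090429
1.16 3.18633
1.165 3.173974
1.17 3.111911
1.175 3.075856
1.18 3.106869
1.185 3.104879
1.19 3.149805
1.195 3.078143
1.2 3.096476
1.205 3.162971
1.21 3.101144
1.215 3.1406
1.22 3.116241
1.225 3.203643
1.23 3.174752
1.235 3.127813
1.24 3.117882
1.245 3.104821
1.25 3.126894
1.255 3.161819
1.26 3.100266
1.265 3.119311
1.27 3.157363
1.275 3.120401
1.28 3.136293
1.285 3.14931
1.29 3.147176
1.295 3.1475
1.3 3.08703
1.305 3.145017
1.31 3.142304
1.315 3.158044
1.32 3.143325
1.325 3.154401
1.33 3.169088
1.335 3.135105
1.34 3.140216
1.345 3.191773
1.35 3.139719
1.355 3.204966
1.36 3.173385
1.365 3.163418
1.37 3.155775
1.375 3.149977
1.38 3.140644
1.385 3.156249
1.39 3.135763
1.395 3.173102
1.4 3.108516
1.405 3.106061
1.41 3.132365
1.415 3.119922
1.42 3.143879
1.425 3.201843
1.43 3.123876
1.435 3.106724
1.44 3.145685
1.445 3.141104
1.45 3.192931
1.455 3.114352
1.46 3.157347
1.465 3.174536
1.47 3.146379
1.475 3.134364
1.48 3.13469
1.485 3.134127
1.49 3.165414
1.495 3.123655
1.5 3.136246
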