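# x U_kJmol
0.33 81.0388
0.335 65.69953
0.34 53.241
0.345 43.11677
0.35 34.96782
0.355 28.3148
0.36 22.87947
0.365 18.36344
0.37 14.75606
0.375 11.73878
0.38 9.230118
0.385 7.218905
0.39 5.555435
0.395 4.228005
0.4 3.14232
0.405 2.37778
0.41 1.651593
0.415 1.2071
0.42 0.7557944
0.425 0.5175685
0.43 0.2407054
0.435 0.1487766
0.44 0.1058922
0.445 0.04474123
0.45 0
0.455 0.03824878
0.46 0.09167465
0.465 0.1383889
0.47 0.2108077
0.475 0.2146665
0.48 0.4065442
0.485 0.3414366
0.49 0.4895888
0.495 0.5313789
0.5 0.6479076
0.505 0.7610154
0.51 0.8084832
0.515 0.9126577
0.52 0.9908284
0.525 1.039315
0.53 1.177085
0.535 1.21704
0.54 1.269644
0.545 1.345709
0.55 1.390449
0.555 1.433249
0.56 1.503541
0.565 1.613206
0.57 1.646864
0.575 1.743968
0.58 1.696555
0.585 1.812135
0.59 1.842657
0.595 1.937701
0.6 1.911431
0.605 1.979164
0.61 2.047141
0.615 2.095632
0.62 2.046512
0.625 2.073812
0.63 2.180525
0.635 2.217971
0.64 2.202056
0.645 2.229204
0.65 2.282672
0.655 2.325455
0.66 2.300437
0.665 2.277794
0.67 2.350838
0.675 2.376294
0.68 2.385212
0.685 2.410443
0.69 2.521983
0.695 2.428916
0.7 2.498932
0.705 2.45306
0.71 2.454093
0.715 2.471103
0.72 2.564862
0.725 2.542361
0.73 2.585965
0.735 2.541207
0.74 2.577335
0.745 2.540272
0.75 2.562319
0.755 2.584771
0.76 2.60001
0.765 2.664493
0.77 2.610849
0.775 2.627752
0.78 2.622608
0.785 2.647982
0.79 2.663124
0.795 2.649758
0.8 2.669975
0.805 2.648731
0.81 2.669929
0.815 2.712781
0.82 2.6576
0.825 2.70277
0.83 2.669055
0.835 2.719167
0.84 2.685631
0.845 2.712507
0.85 2.701628
0.855 2.76718
0.86 2.712777
0.865 2.746547
0.87 2.72101
0.875 2.739555
0.88 2.735876
0.885 2.736088
0.89 2.754834
0.895 2.689712
0.9 2.742248
0.905 2.715445
0.91 2.813331
0.915 2.74246
0.92 2.732607
0.925 2.776622
0.93 2.76584
0.935 2.714707
0.94 2.733844
0.945 2.790557
0.95 2.778371
0.955 2.761761
0.96 2.799293
0.965 2.800367
0.97 2.753792
0.975 2.75722
0.98 2.811944
0.985 2.785436
0.99 2.780429
0.995 2.740843
1 2.780771
1.005 2.78035
1.01 2.799876
1.015 2.773487
1.02 2.747044
1.025 2.762362
1.03 2.790836
1.035 2.817365
1.04 2.78407
1.045 2.792777
1.05 2.816057
1.055 2.765318
1.06 2.877778
1.065 2.820344
1.07 2.800304
1.075 2.741729
1.08 2.739376
1.085 2.766029
1.09 2.795488
1.095 2.785283
1.1 2.824101
1.105 2.845675
1.11 2.80707
1.115 2.816199
1.12 2.821205
1.125 2.836452
1.13 2.801375
1.135 2.789119
1.14 2.837953
1.145 2.799576
1.15 2.793526
1.155 2.810082
1.16 2.795818
1.165 2.816627
1.17 2.798443
1.175 2.820863
1.18 2.815151
1.185 2.802596
1.19 2.81345
1.195 2.834521
1.2 2.841729
1.205 2.820355
1.21 2.801414
1.215 2.85055
1.22 2.841403
1.225 2.780129
1.23 2.779878
1.235 2.863157
1.24 2.823252
1.245 2.82166
1.25 2.780358
1.255 2.762705
1.26 2.881466
1.265 2.809557
1.27 2.81432
1.275 2.796947
1.28 2.838845
1.285 2.853349
1.29 2.821592
1.295 2.742527
1.3 2.835311
1.305 2.841626
1.31 2.855853
1.315 2.853746
1.32 2.794887
1.325 2.814551
1.33 2.799433
1.335 2.861293
1.34 2.792045
1.345 2.811155
1.35 2.768907
1.355 2.801817
1.36 2.88171
1.365 2.84657
1.37 2.731345
1.375 2.768186
1.38 2.843528
1.385 2.804053
1.39 2.860331
1.395 2.813032
1.4 2.846508
1.405 2.799986
1.41 2.781476
1.415 2.808317
1.42 2.819652
1.425 2.795857
1.43 2.853133
1.435 2.796803
1.44 2.764764
1.445 2.824836
1.45 2.861579
1.455 2.83075
1.46 2.819548
1.465 2.887433
1.47 2.848944
1.475 2.852006
1.48 2.82183
1.485 2.828338
1.49 2.809867
1.495 2.851542
1.5 2.797045
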