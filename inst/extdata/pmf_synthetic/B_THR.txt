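# x U_kJmol
0.415 84.82603
0.42 71.67166
0.425 60.53943
0.43 51.1738
0.435 43.20085
0.44 36.48926
0.445 30.74499
0.45 25.85929
0.455 21.61086
0.46 18.06074
0.465 14.96652
0.47 12.39292
0.475 10.18735
0.48 8.315718
0.485 6.707084
0.49 5.372821
0.495 4.313264
0.5 3.38271
0.505 2.632003
0.51 1.925367
0.515 1.517221
0.52 1.122422
0.525 0.7743113
0.53 0.5555713
0.535 0.3629449
0.54 0.2572644
0.545 0.0562046
0.55 0.03946341
0.555 0.04372097
0.56 0.03959246
0.565 0
0.57 0.03074679
0.575 0.05722337
0.58 0.08616104
0.585 0.1762657
0.59 0.2038757
0.595 0.2143037
0.6 0.3937113
0.605 0.3859261
0.61 0.4968209
0.615 0.6161289
0.62 0.6131027
0.625 0.8356796
0.63 0.8316521
0.635 0.9233778
0.64 1.004544
0.645 1.05188
0.65 1.091775
0.655 1.197101
0.66 1.215543
0.665 1.29432
0.67 1.374112
0.675 1.435025
0.68 1.48406
0.685 1.544422
0.69 1.635767
0.695 1.653994
0.7 1.715326
0.705 1.816489
0.71 1.8228
0.715 1.859655
0.72 1.940968
0.725 1.974941
0.73 2.002602
0.735 2.085476
0.74 2.039898
0.745 2.108511
0.75 2.18259
0.755 2.223544
0.76 2.260821
0.765 2.300697
0.77 2.353419
0.775 2.368486
0.78 2.431606
0.785 2.414431
0.79 2.412054
0.795 2.438985
0.8 2.441623
0.805 2.508165
0.81 2.560927
0.815 2.501566
0.82 2.575787
0.825 2.607726
0.83 2.610515
0.835 2.638908
0.84 2.682488
0.845 2.682732
0.85 2.712468
0.855 2.711344
0.86 2.649654
0.865 2.767619
0.87 2.783079
0.875 2.7537
0.88 2.773732
0.885 2.757568
0.89 2.872505
0.895 2.811103
0.9 2.846389
0.905 2.862809
0.91 2.84361
0.915 2.863778
0.92 2.926395
0.925 2.946281
0.93 2.95219
0.935 2.8738
0.94 2.924375
0.945 2.900646
0.95 2.937677
0.955 2.938526
0.96 2.968174
0.965 2.923239
0.97 2.955541
0.975 2.977624
0.98 2.982598
0.985 2.960515
0.99 2.992125
0.995 3.008729
1 3.060226
1.005 3.003054
1.01 2.986467
1.015 3.023259
1.02 3.050519
1.025 3.091896
1.03 3.085415
1.035 3.000347
1.04 3.032164
1.045 3.030448
1.05 3.097091
1.055 3.030843
1.06 3.054909
1.065 3.04266
1.07 3.080685
1.075 3.044448
1.08 3.078646
1.085 3.07146
1.09 3.081383
1.095 3.033707
1.1 3.079219
1.105 3.104734
1.11 3.081015
1.115 3.116781
1.12 3.094217
1.125 3.108283
1.13 3.098187
1.135 3.085387
1.14 3.041034
1.145 3.14887
1.15 3.127732
1.155 3.085992
1.16 3.154519
1.165 3.136368
1.17 3.116475
1.175 3.111222
1.18 3.153315
1.185 3.111557
1.19 3.115196
1.195 3.123411
1.2 3.148278
1.205 3.161737
1.21 3.181857
1.215 3.093083
1.22 3.128671
1.225 3.149265
1.23 3.171734
1.235 3.170475
1.24 3.223996
1.245 3.140394
1.25 3.144603
1.255 3.14347
1.26 3.181001
1.265 3.238683
1.27 3.083876
1.275 3.113256
1.28 3.118949
1.285 3.186624
1.29 3.175507
1.295 3.139984
1.3 3.167507
1.305 3.166393
1.31 3.188026
1.315 3.147208
1.32 3.202415
1.325 3.144022
1.33 3.219513
1.335 3.144832
1.34 3.172195
1.345 3.132592
1.35 3.220235
1.355 3.108318
1.36 3.14063
1.365 3.205358
1.37 3.206685
1.375 3.16112
1.38 3.153859
1.385 3.258299
1.39 3.158122
1.395 3.18075
1.4 3.249978
1.405 3.138896
1.41 3.227345
1.415 3.184506
1.42 3.128862
1.425 3.163017
1.43 3.178436
1.435 3.123953
1.44 3.203433
1.445 3.292145
1.45 3.177726
1.455 3.191667
1.46 3.153756
1.465 3.187108
1.47 3.183798
1.475 3.21061
1.48 3.184023
1.485 3.196218
1.49 3.160221
1.495 3.192775
1.5 3.198358
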