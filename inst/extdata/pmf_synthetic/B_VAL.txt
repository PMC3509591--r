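# x U_kJmol
0.415 105.8202
0.42 89.34657
0.425 75.37753
0.43 63.6509
0.435 53.65537
0.44 45.29606
0.445 38.08816
0.45 31.99536
0.455 26.79173
0.46 22.34898
0.465 18.54243
0.47 15.31905
0.475 12.59129
0.48 10.25836
0.485 8.319907
0.49 6.673886
0.495 5.320881
0.5 4.185543
0.505 3.271938
0.51 2.506261
0.515 1.793117
0.52 1.475703
0.525 1.015447
0.53 0.7530369
0.535 0.4385349
0.54 0.2858623
0.545 0.2429826
0.55 0.1415601
0.555 0.06415204
0.56 0
0.565 0.04308226
0.57 0.08002295
0.575 0.09160374
0.58 0.1441216
0.585 0.1708934
0.59 0.2751729
0.595 0.4089013
0.6 0.4861005
0.605 0.5786977
0.61 0.6121277
0.615 0.6925676
0.62 0.8213004
0.625 0.9283185
0.63 1.035856
0.635 1.091927
0.64 1.229497
0.645 1.365219
0.65 1.384259
0.655 1.501676
0.66 1.570594
0.665 1.674107
0.67 1.657837
0.675 1.864463
0.68 1.907612
0.685 2.034866
0.69 1.966192
0.695 2.171232
0.7 2.199723
0.705 2.255068
0.71 2.350547
0.715 2.400289
0.72 2.411602
0.725 2.5051
0.73 2.588347
0.735 2.606998
0.74 2.677427
0.745 2.754934
0.75 2.791952
0.755 2.759597
0.76 2.853003
0.765 2.920739
0.77 2.9148
0.775 2.988046
0.78 3.043383
0.785 3.078399
0.79 3.049732
0.795 3.055004
0.8 3.219105
0.805 3.173667
0.81 3.215867
0.815 3.256572
0.82 3.254076
0.825 3.327099
0.83 3.343467
0.835 3.356507
0.84 3.346715
0.845 3.37512
0.85 3.396256
0.855 3.384321
0.86 3.495718
0.865 3.506791
0.87 3.482978
0.875 3.483836
0.88 3.571074
0.885 3.564344
0.89 3.534387
0.895 3.557623
0.9 3.553248
0.905 3.628023
0.91 3.65465
0.915 3.667901
0.92 3.632067
0.925 3.602428
0.93 3.625429
0.935 3.602876
0.94 3.687245
0.945 3.751293
0.95 3.732176
0.955 3.749682
0.96 3.690841
0.965 3.679898
0.97 3.756448
0.975 3.760208
0.98 3.776791
0.985 3.76241
0.99 3.793845
0.995 3.79925
1 3.779668
1.005 3.783564
1.01 3.847079
1.015 3.788387
1.02 3.823381
1.025 3.810134
1.03 3.850499
1.035 3.887853
1.04 3.792638
1.045 3.858407
1.05 3.845066
1.055 3.850303
1.06 3.839469
1.065 3.887139
1.07 3.833607
1.075 3.879733
1.08 3.889451
1.085 3.886509
1.09 3.872426
1.095 3.895862
1.1 3.866215
1.105 3.887198
1.11 3.921042
1.115 3.922849
1.12 3.904247
1.125 3.878217
1.13 3.846505
1.135 3.893481
1.14 3.953653
1.145 3.904358
1.15 3.870489
1.155 3.926486
1.16 3.947557
1.165 3.976326
1.17 3.945827
1.175 3.92368
1.18 3.94196
1.185 3.96293
1.19 3.958537
1.195 3.931559
1.2 3.945306
1.205 3.988344
1.21 3.90908
1.215 3.915909
1.22 4.019964
1.225 3.945372
1.23 3.989757
1.235 3.924999
1.24 3.953323
1.245 3.977503
1.25 4.022181
1.255 3.959317
1.26 3.993262
1.265 3.97316
1.27 4.009849
1.275 4.003646
1.28 3.958816
1.285 3.983779
1.29 3.98667
1.295 3.977979
1.3 3.957797
1.305 3.99606
1.31 4.00251
1.315 3.964912
1.32 3.978352
1.325 3.984189
1.33 4.025119
1.335 3.984407
1.34 3.95402
1.345 3.950812
1.35 4.040621
1.355 4.010624
1.36 3.976619
1.365 3.962521
1.37 3.994422
1.375 4.019727
1.38 3.980832
1.385 4.018223
1.39 4.017592
1.395 4.004935
1.4 3.99543
1.405 4.027594
1.41 4.010837
1.415 3.937118
1.42 4.022095
1.425 3.984852
1.43 4.044134
1.435 3.981732
1.44 3.971468
1.445 4.007631
1.45 4.026496
1.455 4.05486
1.46 4.032357
1.465 4.024016
1.47 4.084755
1.475 4.020588
1.48 3.993948
1.485 4.017996
1.49 4.012506
1.495 4.003914
1.5 3.990899
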