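# x U_kJmol
0.37 90.7929
0.375 75.29326
0.38 62.48946
0.385 51.76376
0.39 43.0342
0.395 35.6722
0.4 29.50161
0.405 24.37435
0.41 20.0373
0.415 16.34223
0.42 13.3484
0.425 10.78638
0.43 8.684207
0.435 6.959688
0.44 5.471662
0.445 4.235904
0.45 3.279366
0.455 2.538856
0.46 1.797761
0.465 1.255952
0.47 0.9250524
0.475 0.6458516
0.48 0.4136275
0.485 0.3186961
0.49 0.116109
0.495 0.08682869
0.5 0.06119609
0.505 0
0.51 0.07631126
0.515 0.03445601
0.52 0.09245133
0.525 0.1489973
0.53 0.1428705
0.535 0.2211707
0.54 0.3355767
0.545 0.3970879
0.55 0.5162049
0.555 0.5663388
0.56 0.6743838
0.565 0.7276926
0.57 0.8257665
0.575 0.922074
0.58 0.9662985
0.585 1.002151
0.59 1.135467
0.595 1.164734
0.6 1.194024
0.605 1.259954
0.61 1.402869
0.615 1.45673
0.62 1.503309
0.625 1.626015
0.63 1.65546
0.635 1.672816
0.64 1.760077
0.645 1.820647
0.65 1.793751
0.655 1.900506
0.66 1.867566
0.665 1.967126
0.67 2.047466
0.675 2.071222
0.68 2.078958
0.685 2.138507
0.69 2.164596
0.695 2.20303
0.7 2.211968
0.705 2.278444
0.71 2.244694
0.715 2.323694
0.72 2.319933
0.725 2.342921
0.73 2.377419
0.735 2.424602
0.74 2.454685
0.745 2.461603
0.75 2.487041
0.755 2.48787
0.76 2.520771
0.765 2.547266
0.77 2.565175
0.775 2.63958
0.78 2.559423
0.785 2.582711
0.79 2.623236
0.795 2.661348
0.8 2.658123
0.805 2.670976
0.81 2.68809
0.815 2.732221
0.82 2.726659
0.825 2.812684
0.83 2.746743
0.835 2.709216
0.84 2.709562
0.845 2.79194
0.85 2.778015
0.855 2.75791
0.86 2.79603
0.865 2.815038
0.87 2.802372
0.875 2.77829
0.88 2.826715
0.885 2.821584
0.89 2.878684
0.895 2.797654
0.9 2.856604
0.905 2.832008
0.91 2.839882
0.915 2.869643
0.92 2.920372
0.925 2.839019
0.93 2.878961
0.935 2.907189
0.94 2.896316
0.945 2.846775
0.95 2.836387
0.955 2.915067
0.96 2.881858
0.965 2.896648
0.97 2.884661
0.975 2.870433
0.98 2.882767
0.985 2.988818
0.99 2.859785
0.995 2.947468
1 2.912512
1.005 2.896039
1.01 2.951633
1.015 2.917674
1.02 2.877437
1.025 2.863668
1.03 2.920637
1.035 2.975967
1.04 2.957677
1.045 2.914743
1.05 2.925399
1.055 2.999837
1.06 2.940423
1.065 2.924399
1.07 2.946548
1.075 2.942557
1.08 2.980963
1.085 3.005646
1.09 2.977692
1.095 2.92502
1.1 2.921901
1.105 2.945365
1.11 2.924507
1.115 3.002409
1.12 2.952856
1.125 2.97595
1.13 2.939726
1.135 2.985663
1.14 3.004698
1.145 2.989923
1.15 2.95733
1.155 2.948056
1.16 2.989125
1.165 2.973956
1.17 2.990554
1.175 2.919691
1.18 2.946053
1.185 3.010704
1.19 3.015305
1.195 2.946391
1.2 2.974765
1.205 2.896124
1.21 2.97486
1.215 3.009822
1.22 3.001746
1.225 2.999783
1.23 3.032355
1.235 2.988564
1.24 3.003336
1.245 3.024213
1.25 2.995403
1.255 2.957651
1.26 2.988166
1.265 2.994075
1.27 3.00144
1.275 2.985698
1.28 2.937252
1.285 3.013657
1.29 2.953513
1.295 2.941392
1.3 2.975422
1.305 2.946947
1.31 2.95343
1.315 2.929382
1.32 3.026888
1.325 3.021471
1.33 3.016239
1.335 2.992436
1.34 3.028956
1.345 2.954265
1.35 2.979871
1.355 2.997962
1.36 2.960324
1.365 2.97352
1.37 2.967896
1.375 2.967949
1.38 2.970061
1.385 3.075082
1.39 3.005797
1.395 3.008099
1.4 2.970867
1.405 3.018695
1.41 2.958018
1.415 3.033447
1.42 3.024276
1.425 2.967378
1.43 3.012498
1.435 2.995333
1.44 2.991175
1.445 2.978212
1.45 3.041046
1.455 3.003279
1.46 2.9641
1.465 2.987346
1.47 3.026997
1.475 3.016537
1.48 3.046347
1.485 3.029267
1.49 2.989775
1.495 3.054752
1.5 3.006112
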