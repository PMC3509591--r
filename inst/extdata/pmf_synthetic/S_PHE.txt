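# x U_kJmol
0.37 144.7913
0.375 119.8259
0.38 99.15966
0.385 82.08686
0.39 67.9062
0.395 56.09719
0.4 46.30755
0.405 38.08964
0.41 31.24019
0.415 25.57286
0.42 20.80113
0.425 16.76941
0.43 13.49642
0.435 10.73846
0.44 8.438065
0.445 6.559255
0.45 5.093545
0.455 3.830123
0.46 2.821266
0.465 2.056802
0.47 1.408502
0.475 1.025149
0.48 0.6878556
0.485 0.4359294
0.49 0.2543413
0.495 0.1165703
0.5 0.08373148
0.505 0
0.51 0.004573684
0.515 0.07967052
0.52 0.1209179
0.525 0.2613913
0.53 0.3242652
0.535 0.3614463
0.54 0.5257066
0.545 0.7010972
0.55 0.8161569
0.555 0.8938363
0.56 1.035989
0.565 1.184363
0.57 1.310791
0.575 1.452641
0.58 1.538562
0.585 1.649074
0.59 1.794079
0.595 1.947293
0.6 2.035196
0.605 2.051632
0.61 2.241414
0.615 2.291976
0.62 2.475675
0.625 2.516857
0.63 2.594368
0.635 2.717256
0.64 2.765337
0.645 2.874753
0.65 2.889958
0.655 3.04293
0.66 3.081852
0.665 3.159316
0.67 3.211828
0.675 3.314016
0.68 3.295163
0.685 3.393433
0.69 3.466818
0.695 3.54772
0.7 3.558452
0.705 3.568709
0.71 3.663715
0.715 3.702237
0.72 3.705359
0.725 3.746681
0.73 3.877559
0.735 3.834391
0.74 3.91594
0.745 3.935027
0.75 3.992621
0.755 4.03372
0.76 4.046543
0.765 4.05902
0.77 4.080843
0.775 4.120829
0.78 4.198359
0.785 4.095507
0.79 4.144155
0.795 4.235898
0.8 4.182242
0.805 4.231891
0.81 4.248988
0.815 4.329566
0.82 4.371228
0.825 4.334636
0.83 4.317392
0.835 4.367987
0.84 4.378104
0.845 4.39271
0.85 4.428678
0.855 4.428688
0.86 4.469527
0.865 4.42323
0.87 4.41569
0.875 4.444735
0.88 4.514045
0.885 4.442806
0.89 4.499195
0.895 4.519169
0.9 4.543523
0.905 4.542592
0.91 4.543729
0.915 4.538223
0.92 4.578843
0.925 4.506729
0.93 4.575387
0.935 4.573952
0.94 4.55611
0.945 4.556705
0.95 4.602946
0.955 4.613843
0.96 4.670721
0.965 4.656317
0.97 4.630564
0.975 4.67053
0.98 4.663311
0.985 4.666565
0.99 4.611691
0.995 4.651526
1 4.630493
1.005 4.633202
1.01 4.682464
1.015 4.667156
1.02 4.643796
1.025 4.681398
1.03 4.617565
1.035 4.688089
1.04 4.694118
1.045 4.664874
1.05 4.715551
1.055 4.763211
1.06 4.694321
1.065 4.739912
1.07 4.70123
1.075 4.715734
1.08 4.649682
1.085 4.746319
1.09 4.676702
1.095 4.753316
1.1 4.769395
1.105 4.734519
1.11 4.746449
1.115 4.728468
1.12 4.718454
1.125 4.791378
1.13 4.656345
1.135 4.783217
1.14 4.713852
1.145 4.733206
1.15 4.760602
1.155 4.723032
1.16 4.747154
1.165 4.75629
1.17 4.751352
1.175 4.752976
1.18 4.734023
1.185 4.78655
1.19 4.779176
1.195 4.791507
1.2 4.76254
1.205 4.772762
1.21 4.754827
1.215 4.779062
1.22 4.758098
1.225 4.742487
1.23 4.755594
1.235 4.794903
1.24 4.77535
1.245 4.749901
1.25 4.791967
1.255 4.810619
1.26 4.778036
1.265 4.747399
1.27 4.812638
1.275 4.752966
1.28 4.776744
1.285 4.753376
1.29 4.789625
1.295 4.814385
1.3 4.800935
1.305 4.805482
1.31 4.818672
1.315 4.771327
1.32 4.729159
1.325 4.779376
1.33 4.805953
1.335 4.73896
1.34 4.783305
1.345 4.775487
1.35 4.760793
1.355 4.797863
1.36 4.742424
1.365 4.746766
1.37 4.76156
1.375 4.743652
1.38 4.766607
1.385 4.767614
1.39 4.843199
1.395 4.789139
1.4 4.744151
1.405 4.856219
1.41 4.796586
1.415 4.805421
1.42 4.808921
1.425 4.808604
1.43 4.786654
1.435 4.830524
1.44 4.81562
1.445 4.82718
1.45 4.813822
1.455 4.79271
1.46 4.868437
1.465 4.793106
1.47 4.789853
1.475 4.777381
1.48 4.825317
1.485 4.805938
1.49 4.799735
1.495 4.82685
1.5 4.793338
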