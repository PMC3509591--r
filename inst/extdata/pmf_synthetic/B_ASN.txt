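# x U_kJmol
0.495 97.88706
0.5 85.01926
0.505 73.82972
0.51 64.24579
0.515 55.83025
0.52 48.516
0.525 42.21037
0.53 36.58909
0.535 31.65311
0.54 27.41384
0.545 23.60599
0.55 20.20827
0.555 17.33987
0.56 14.7929
0.565 12.56408
0.57 10.58657
0.575 8.903657
0.58 7.490559
0.585 6.256854
0.59 5.173177
0.595 4.230139
0.6 3.49006
0.605 2.841257
0.61 2.268267
0.615 1.795394
0.62 1.454013
0.625 1.166872
0.63 0.8674221
0.635 0.6357516
0.64 0.4774651
0.645 0.3603746
0.65 0.209353
0.655 0.1784307
0.66 0.1227538
0.665 0.02982375
0.67 0.04175743
0.675 0
0.68 0.06838195
0.685 0.04730755
0.69 0.09319856
0.695 0.154243
0.7 0.145604
0.705 0.2949058
0.71 0.2761053
0.715 0.3721005
0.72 0.3817887
0.725 0.5265997
0.73 0.4630054
0.735 0.578278
0.74 0.6787444
0.745 0.7134188
0.75 0.8671571
0.755 0.9229625
0.76 0.9308484
0.765 0.9810676
0.77 1.048971
0.775 1.123862
0.78 1.218222
0.785 1.267987
0.79 1.354087
0.795 1.394301
0.8 1.396399
0.805 1.483824
0.81 1.56818
0.815 1.596081
0.82 1.720205
0.825 1.694446
0.83 1.813626
0.835 1.79594
0.84 1.841012
0.845 1.926149
0.85 1.949145
0.855 2.035844
0.86 2.056344
0.865 2.094095
0.87 2.121831
0.875 2.213882
0.88 2.225758
0.885 2.258968
0.89 2.204013
0.895 2.285022
0.9 2.385562
0.905 2.359036
0.91 2.424199
0.915 2.474572
0.92 2.435339
0.925 2.434246
0.93 2.473107
0.935 2.601105
0.94 2.583641
0.945 2.585118
0.95 2.633306
0.955 2.647742
0.96 2.681933
0.965 2.674552
0.97 2.77007
0.975 2.711575
0.98 2.806383
0.985 2.767394
0.99 2.872776
0.995 2.835012
1 2.811288
1.005 2.84433
1.01 2.847832
1.015 2.838633
1.02 2.900605
1.025 2.881384
1.03 2.94568
1.035 2.915817
1.04 2.971492
1.045 2.940906
1.05 2.98049
1.055 2.987022
1.06 3.043805
1.065 2.985672
1.07 3.029525
1.075 3.071046
1.08 3.095221
1.085 3.090076
1.09 3.072098
1.095 3.077404
1.1 3.11039
1.105 3.118237
1.11 3.07796
1.115 3.140172
1.12 3.148547
1.125 3.134781
1.13 3.193562
1.135 3.123736
1.14 3.117314
1.145 3.20766
1.15 3.219331
1.155 3.211111
1.16 3.196202
1.165 3.225297
1.17 3.237074
1.175 3.237582
1.18 3.235609
1.185 3.20405
1.19 3.272002
1.195 3.223723
1.2 3.195005
1.205 3.284702
1.21 3.276893
1.215 3.233691
1.22 3.258224
1.225 3.230307
1.23 3.22945
1.235 3.324313
1.24 3.290859
1.245 3.284015
1.25 3.308712
1.255 3.247198
1.26 3.244156
1.265 3.290715
1.27 3.306862
1.275 3.284956
1.28 3.342991
1.285 3.31102
1.29 3.3037
1.295 3.286078
1.3 3.352831
1.305 3.323181
1.31 3.288461
1.315 3.293265
1.32 3.274401
1.325 3.305914
1.33 3.29038
1.335 3.317395
1.34 3.321025
1.345 3.350822
1.35 3.340501
1.355 3.34689
1.36 3.371191
1.365 3.344981
1.37 3.399764
1.375 3.311267
1.38 3.323704
1.385 3.308666
1.39 3.381606
1.395 3.353434
1.4 3.369489
1.405 3.362507
1.41 3.353246
1.415 3.355123
1.42 3.384328
1.425 3.402337
1.43 3.373511
1.435 3.333075
1.44 3.362895
1.445 3.339186
1.45 3.346007
1.455 3.373482
1.46 3.357466
1.465 3.374422
1.47 3.342439
1.475 3.405765
1.48 3.353551
1.485 3.432836
1.49 3.419047
1.495 3.378485
1.5 3.356498
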