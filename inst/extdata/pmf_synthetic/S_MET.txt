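# x U_kJmol
0.37 126.7729
0.375 104.9797
0.38 86.95175
0.385 72.04487
0.39 59.60475
0.395 49.27759
0.4 40.64616
0.405 33.49768
0.41 27.49358
0.415 22.53872
0.42 18.342
0.425 14.78863
0.43 11.87406
0.435 9.418729
0.44 7.513367
0.445 5.853296
0.45 4.512515
0.455 3.425952
0.46 2.527457
0.465 1.856226
0.47 1.354457
0.475 0.9409947
0.48 0.5726359
0.485 0.3869553
0.49 0.21713
0.495 0.1176825
0.5 0.0363614
0.505 0.0595136
0.51 0
0.515 0.04449225
0.52 0.1769867
0.525 0.1797991
0.53 0.3095853
0.535 0.3570199
0.54 0.481929
0.545 0.6312233
0.55 0.7424297
0.555 0.8265324
0.56 0.9561731
0.565 1.047484
0.57 1.189926
0.575 1.269795
0.58 1.336989
0.585 1.451199
0.59 1.582308
0.595 1.674632
0.6 1.7934
0.605 1.894854
0.61 2.026351
0.615 2.102082
0.62 2.148661
0.625 2.221924
0.63 2.296423
0.635 2.36457
0.64 2.418104
0.645 2.524077
0.65 2.54753
0.655 2.631454
0.66 2.707565
0.665 2.802322
0.67 2.846315
0.675 2.917665
0.68 2.89016
0.685 3.011733
0.69 3.061373
0.695 3.031225
0.7 3.092108
0.705 3.152603
0.71 3.288792
0.715 3.294782
0.72 3.265695
0.725 3.323326
0.73 3.361574
0.735 3.460473
0.74 3.438976
0.745 3.468872
0.75 3.457228
0.755 3.514718
0.76 3.53931
0.765 3.539235
0.77 3.594698
0.775 3.59611
0.78 3.642628
0.785 3.680844
0.79 3.717895
0.795 3.741551
0.8 3.717082
0.805 3.746873
0.81 3.813862
0.815 3.825374
0.82 3.81018
0.825 3.816761
0.83 3.833324
0.835 3.823725
0.84 3.849506
0.845 3.851392
0.85 3.894232
0.855 3.878309
0.86 3.919857
0.865 3.955452
0.87 3.932445
0.875 3.931633
0.88 3.927341
0.885 3.91738
0.89 3.964672
0.895 3.981446
0.9 3.98396
0.905 3.958584
0.91 4.012148
0.915 4.053172
0.92 3.982797
0.925 3.955363
0.93 3.982633
0.935 4.023979
0.94 4.011082
0.945 4.068424
0.95 4.026445
0.955 4.076102
0.96 3.979863
0.965 4.101382
0.97 4.094803
0.975 4.100574
0.98 4.12871
0.985 4.108886
0.99 4.13803
0.995 4.047325
1 4.105951
1.005 4.153397
1.01 4.110793
1.015 4.126214
1.02 4.162478
1.025 4.137856
1.03 4.071342
1.035 4.113942
1.04 4.13811
1.045 4.131718
1.05 4.120557
1.055 4.121227
1.06 4.168312
1.065 4.120869
1.07 4.134325
1.075 4.112506
1.08 4.172907
1.085 4.114606
1.09 4.107098
1.095 4.162805
1.1 4.152676
1.105 4.195857
1.11 4.199349
1.115 4.20163
1.12 4.215039
1.125 4.136106
1.13 4.156847
1.135 4.197719
1.14 4.135653
1.145 4.132691
1.15 4.160405
1.155 4.178124
1.16 4.192392
1.165 4.195654
1.17 4.210897
1.175 4.195862
1.18 4.190258
1.185 4.24768
1.19 4.213142
1.195 4.158363
1.2 4.191681
1.205 4.191235
1.21 4.173196
1.215 4.202837
1.22 4.180042
1.225 4.197128
1.23 4.144354
1.235 4.17909
1.24 4.235246
1.245 4.279183
1.25 4.20107
1.255 4.185073
1.26 4.224368
1.265 4.183723
1.27 4.220041
1.275 4.205689
1.28 4.201374
1.285 4.177497
1.29 4.221117
1.295 4.159174
1.3 4.19577
1.305 4.243887
1.31 4.198753
1.315 4.272785
1.32 4.180734
1.325 4.170839
1.33 4.233456
1.335 4.18044
1.34 4.231417
1.345 4.24032
1.35 4.230671
1.355 4.209318
1.36 4.182656
1.365 4.180325
1.37 4.197288
1.375 4.16579
1.38 4.17403
1.385 4.218284
1.39 4.252586
1.395 4.23122
1.4 4.260405
1.405 4.219686
1.41 4.15797
1.415 4.218667
1.42 4.172531
1.425 4.214071
1.43 4.153265
1.435 4.281597
1.44 4.240629
1.445 4.216374
1.45 4.231082
1.455 4.256077
1.46 4.307802
1.465 4.273426
1.47 4.245968
1.475 4.221252
1.48 4.229186
1.485 4.240743
1.49 4.236038
1.495 4.21616
1.5 4.196511
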