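pc,metric,svc,qsvc
9,TPR,0.333,0.333
9,SPC,0.768,0.775
9,PPV,0.238,0.244
9,F1,0.278,0.282
9,ACC,0.69,0.696
9,NPV,0.841,0.842
9,FPR,0.23,0.224
9,FDR,0.762,0.756
9,FNR,0.667,0.666
9,MCC,0.089,0.097
10,TPR,0.567,0.633
10,SPC,0.746,0.739
10,PPV,0.327,0.345
10,F1,0.415,0.447
10,ACC,0.714,0.720
10,NPV,0.888,0.903
10,FPR,0.254,0.261
10,FDR,0.673,0.654
10,FNR,0.433,0.366
10,MCC,0.259,0.304
11,TPR,0.4,0.3
11,SPC,0.789,0.797
11,PPV,0.293,0.243
11,F1,0.338,0.269
11,ACC,0.720,0.708
11,NPV,0.858,0.839
11,FPR,0.210,0.203
11,FDR,0.707,0.757
11,FNR,0.6,0.7
11,MCC,0.169,0.089
12,TPR,0.2,0.233
12,SPC,0.811,0.775
12,PPV,0.187,0.184
12,F1,0.193,0.206
12,ACC,0.702,0.678
12,NPV,0.823,0.823
12,FPR,0.188,0.225
12,FDR,0.812,0.816
12,FNR,0.8,0.766
12,MCC,0.011,0.008
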