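sex,agemos,L,M,S
male,24,-2.2,16.3032,0.08
male,25,-2.206,16.27125,0.08018
male,26,-2.212,16.2402,0.08036
male,27,-2.218,16.21005,0.08054
male,28,-2.224,16.1808,0.08072
male,29,-2.23,16.15245,0.0809
male,30,-2.236,16.125,0.08108
male,31,-2.242,16.09845,0.08126
male,32,-2.248,16.0728,0.08144
male,33,-2.254,16.04805,0.08162
male,34,-2.26,16.0242,0.0818
male,35,-2.266,16.00125,0.08198
male,36,-2.272,15.9792,0.08216
male,37,-2.278,15.95805,0.08234
male,38,-2.284,15.9378,0.08252
male,39,-2.29,15.91845,0.0827
male,40,-2.296,15.9,0.08288
male,41,-2.302,15.88245,0.08306
male,42,-2.308,15.8658,0.08324
male,43,-2.314,15.85005,0.08342
male,44,-2.32,15.8352,0.0836
male,45,-2.326,15.82125,0.08378
male,46,-2.332,15.8082,0.08396
male,47,-2.338,15.79605,0.08414
male,48,-2.344,15.7848,0.08432
male,49,-2.35,15.77445,0.0845
male,50,-2.356,15.765,0.08468
male,51,-2.362,15.75645,0.08486
male,52,-2.368,15.7488,0.08504
male,53,-2.374,15.74205,0.08522
male,54,-2.38,15.7362,0.0854
male,55,-2.386,15.73125,0.08558
male,56,-2.392,15.7272,0.08576
male,57,-2.398,15.72405,0.08594
male,58,-2.404,15.7218,0.08612
male,59,-2.41,15.72045,0.0863
male,60,-2.416,15.72,0.08648
male,61,-2.422,15.72045,0.08666
male,62,-2.428,15.7218,0.08684
male,63,-2.434,15.72405,0.08702
male,64,-2.44,15.7272,0.0872
male,65,-2.446,15.73125,0.08738
male,66,-2.452,15.7362,0.08756
male,67,-2.458,15.74205,0.08774
male,68,-2.464,15.7488,0.08792
male,69,-2.47,15.75645,0.0881
male,70,-2.476,15.765,0.08828
male,71,-2.482,15.77445,0.08846
male,72,-2.488,15.7848,0.08864
male,73,-2.494,15.79605,0.08882
male,74,-2.5,15.8082,0.089
male,75,-2.506,15.82125,0.08918
male,76,-2.512,15.8352,0.08936
male,77,-2.518,15.85005,0.08954
male,78,-2.524,15.8658,0.08972
male,79,-2.53,15.88245,0.0899
male,80,-2.536,15.9,0.09008
male,81,-2.542,15.91845,0.09026
male,82,-2.548,15.9378,0.09044
male,83,-2.554,15.95805,0.09062
male,84,-2.56,15.9792,0.0908
female,24,-2.05,16.0832,0.084
female,25,-2.056,16.05125,0.08418
female,26,-2.062,16.0202,0.08436
female,27,-2.068,15.99005,0.08454
female,28,-2.074,15.9608,0.08472
female,29,-2.08,15.93245,0.0849
female,30,-2.086,15.905,0.08508
female,31,-2.092,15.87845,0.08526
female,32,-2.098,15.8528,0.08544
female,33,-2.104,15.82805,0.08562
female,34,-2.11,15.8042,0.0858
female,35,-2.116,15.78125,0.08598
female,36,-2.122,15.7592,0.08616
female,37,-2.128,15.73805,0.08634
female,38,-2.134,15.7178,0.08652
female,39,-2.14,15.69845,0.0867
female,40,-2.146,15.68,0.08688
female,41,-2.152,15.66245,0.08706
female,42,-2.158,15.6458,0.08724
female,43,-2.164,15.63005,0.08742
female,44,-2.17,15.6152,0.0876
female,45,-2.176,15.60125,0.08778
female,46,-2.182,15.5882,0.08796
female,47,-2.188,15.57605,0.08814
female,48,-2.194,15.5648,0.08832
female,49,-2.2,15.55445,0.0885
female,50,-2.206,15.545,0.08868
female,51,-2.212,15.53645,0.08886
female,52,-2.218,15.5288,0.08904
female,53,-2.224,15.52205,0.08922
female,54,-2.23,15.5162,0.0894
female,55,-2.236,15.51125,0.08958
female,56,-2.242,15.5072,0.08976
female,57,-2.248,15.50405,0.08994
female,58,-2.254,15.5018,0.09012
female,59,-2.26,15.50045,0.0903
female,60,-2.266,15.5,0.09048
female,61,-2.272,15.50045,0.09066
female,62,-2.278,15.5018,0.09084
female,63,-2.284,15.50405,0.09102
female,64,-2.29,15.5072,0.0912
female,65,-2.296,15.51125,0.09138
female,66,-2.302,15.5162,0.09156
female,67,-2.308,15.52205,0.09174
female,68,-2.314,15.5288,0.09192
female,69,-2.32,15.53645,0.0921
female,70,-2.326,15.545,0.09228
female,71,-2.332,15.55445,0.09246
female,72,-2.338,15.5648,0.09264
female,73,-2.344,15.57605,0.09282
female,74,-2.35,15.5882,0.093
female,75,-2.356,15.60125,0.09318
female,76,-2.362,15.6152,0.09336
female,77,-2.368,15.63005,0.09354
female,78,-2.374,15.6458,0.09372
female,79,-2.38,15.66245,0.0939
female,80,-2.386,15.68,0.09408
female,81,-2.392,15.69845,0.09426
female,82,-2.398,15.7178,0.09444
female,83,-2.404,15.73805,0.09462
female,84,-2.41,15.7592,0.0948
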