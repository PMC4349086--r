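"position","luminance"
0,1.26013259450068
0.0101010101010101,1.28978687474669
0.0202020202020202,1.30221028668343
0.0303030303030303,1.29831312757059
0.0404040404040404,1.29056112252742
0.0505050505050505,1.28240196652
0.0606060606060606,1.27756829701558
0.0707070707070707,1.27526425983728
0.0808080808080808,1.27583221559748
0.0909090909090909,1.27736528273947
0.101010101010101,1.27690095550418
0.111111111111111,1.27576606126639
0.121212121212121,1.27549086410309
0.131313131313131,1.27605616824774
0.141414141414141,1.27570060338416
0.151515151515152,1.27564986843885
0.161616161616162,1.27677042371382
0.171717171717172,1.27763186315447
0.181818181818182,1.27714388663846
0.191919191919192,1.27777024023972
0.202020202020202,1.27858674263914
0.212121212121212,1.27841156174339
0.222222222222222,1.27831417731261
0.232323232323232,1.27800069059602
0.242424242424242,1.27792109025268
0.252525252525253,1.27758923266703
0.262626262626263,1.27622605304112
0.272727272727273,1.27553734071561
0.282828282828283,1.27456456964767
0.292929292929293,1.27296064982262
0.303030303030303,1.27048883833075
0.313131313131313,1.26774946530047
0.323232323232323,1.2642495636318
0.333333333333333,1.25960989431434
0.343434343434343,1.25471332916576
0.353535353535354,1.24902595213274
0.363636363636364,1.24279233488212
0.373737373737374,1.23571073288449
0.383838383838384,1.22729523465001
0.393939393939394,1.2176064354959
0.404040404040404,1.20715643856292
0.414141414141414,1.19570556321732
0.424242424242424,1.18274721174322
0.434343434343434,1.16821483746016
0.444444444444444,1.1524856509145
0.454545454545455,1.13539877430725
0.464646464646465,1.11702474246493
0.474747474747475,1.09755065909511
0.484848484848485,1.07760657847481
0.494949494949495,1.05683927743038
0.505050505050505,1.03573093427883
0.515151515151515,1.01391636378285
0.525252525252525,0.991767553460345
0.535353535353535,0.969425627384056
0.545454545454546,0.94815954791969
0.555555555555556,0.927549918354839
0.565656565656566,0.90791716532979
0.575757575757576,0.889167516086355
0.585858585858586,0.871256644853933
0.595959595959596,0.853837495401859
0.606060606060606,0.837417274099332
0.616161616161616,0.822374301721673
0.626262626262626,0.808527843900534
0.636363636363636,0.795667514980523
0.646464646464647,0.78391752793094
0.656565656565657,0.772517426040964
0.666666666666667,0.762558645016877
0.676767676767677,0.752695773774562
0.686868686868687,0.743593899442046
0.696969696969697,0.735437061463621
0.707070707070707,0.728185711045287
0.717171717171717,0.721016178293705
0.727272727272727,0.714868339702427
0.737373737373737,0.709041843878045
0.747474747474748,0.703510761395451
0.757575757575758,0.69922311768512
0.767676767676768,0.695699637936526
0.777777777777778,0.692068595878606
0.787878787878788,0.68918610476895
0.797979797979798,0.686544120386316
0.808080808080808,0.684359625587357
0.818181818181818,0.682325728857077
0.828282828282828,0.680458090204633
0.838383838383838,0.678717280327838
0.848484848484849,0.677808207775513
0.858585858585859,0.676723291510487
0.868686868686869,0.675866632019105
0.878787878787879,0.674881494533058
0.888888888888889,0.67446425123341
0.898989898989899,0.673848916965116
0.909090909090909,0.672959353631057
0.919191919191919,0.672279553917088
0.929292929292929,0.672151428296924
0.939393939393939,0.672022998973344
0.94949494949495,0.671792387920107
0.95959595959596,0.671224461491816
0.96969696969697,0.670904424296546
0.97979797979798,0.670927586836418
0.98989898989899,0.670920363852991
1,0.67018289024965
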