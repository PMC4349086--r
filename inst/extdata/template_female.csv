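"position","luminance"
0,1.05407810185504
0.0101010101010101,1.05629508794185
0.0202020202020202,1.04971419912312
0.0303030303030303,1.0362701773579
0.0404040404040404,1.01890721778459
0.0505050505050505,1.00053376699747
0.0606060606060606,0.984593195121408
0.0707070707070707,0.970253235190324
0.0808080808080808,0.957646401465467
0.0909090909090909,0.946849663306455
0.101010101010101,0.93763336445115
0.111111111111111,0.930525708479334
0.121212121212121,0.924647380583815
0.131313131313131,0.92063306709356
0.141414141414141,0.918973925045628
0.151515151515152,0.919612318378145
0.161616161616162,0.92315334318362
0.171717171717172,0.928842577159013
0.181818181818182,0.935221162515975
0.191919191919192,0.943730300588103
0.202020202020202,0.953657027747448
0.212121212121212,0.964547224017101
0.222222222222222,0.975391460871851
0.232323232323232,0.986570017717421
0.242424242424242,0.997198746970408
0.252525252525253,1.00652615675085
0.262626262626263,1.01462635902332
0.272727272727273,1.0219265327632
0.282828282828283,1.02739375096095
0.292929292929293,1.03064597212107
0.303030303030303,1.03172406005015
0.313131313131313,1.02996087345664
0.323232323232323,1.02603322193948
0.333333333333333,1.0206564899687
0.343434343434343,1.01314483709567
0.353535353535354,1.00408395195034
0.363636363636364,0.994402120294453
0.373737373737374,0.983677069754745
0.383838383838384,0.972621260374333
0.393939393939394,0.961516579003493
0.404040404040404,0.950992287051704
0.414141414141414,0.941003054158409
0.424242424242424,0.933179013675307
0.434343434343434,0.926714611333267
0.444444444444444,0.921872025754396
0.454545454545455,0.919029083375682
0.464646464646465,0.919000012527153
0.474747474747475,0.921511101952819
0.484848484848485,0.926114634280498
0.494949494949495,0.933018128389595
0.505050505050505,0.941927997837978
0.515151515151515,0.952461409593222
0.525252525252525,0.964649589158383
0.535353535353535,0.978113479203563
0.545454545454546,0.99212678244216
0.555555555555556,1.00693894296333
0.565656565656566,1.02137951980756
0.575757575757576,1.03467382357211
0.585858585858586,1.04723378349836
0.595959595959596,1.05815275369303
0.606060606060606,1.06791385674029
0.616161616161616,1.0750618571356
0.626262626262626,1.07959562664721
0.636363636363636,1.08183301293324
0.646464646464647,1.0814495981779
0.656565656565657,1.07891768054316
0.666666666666667,1.07400875456198
0.676767676767677,1.06671007278676
0.686868686868687,1.05717121984736
0.696969696969697,1.04588403675525
0.707070707070707,1.03427921479455
0.717171717171717,1.02157794725336
0.727272727272727,1.00929710911216
0.737373737373737,0.99800497314709
0.747474747474748,0.987316736928254
0.757575757575758,0.978115001230403
0.767676767676768,0.971127755834253
0.777777777777778,0.96645265278721
0.787878787878788,0.964421623388323
0.797979797979798,0.964577114939547
0.808080808080808,0.966899890290496
0.818181818181818,0.971662046313927
0.828282828282828,0.978964842617288
0.838383838383838,0.987910345728263
0.848484848484849,0.998009297364858
0.858585858585859,1.00897159309568
0.868686868686869,1.02046776126254
0.878787878787879,1.0321572990998
0.888888888888889,1.04368869041994
0.898989898989899,1.05443846594631
0.909090909090909,1.06305986245206
0.919191919191919,1.07000647999784
0.929292929292929,1.07493494199685
0.939393939393939,1.07792589356051
0.94949494949495,1.07785297680102
0.95959595959596,1.07522447512038
0.96969696969697,1.07091073142856
0.97979797979798,1.06391594785459
0.98989898989899,1.05402134798143
1,1.04075132440161
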