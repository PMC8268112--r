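# screensim country parameter bundle.
# Policy parameters (sensitivity, referral, observed coverage) are published
# programme values; natural-history, survival and demography parameters are
# SYNTHETIC stand-ins, not calibrated national estimates.

name: slovenia
life_table:
  age:
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  q:
  - 0.001399020457173
  - 0.001553786476421
  - 0.001725658619938
  - 0.001916524153041
  - 0.002128477749663
  - 0.002363844097588
  - 0.002625202923182
  - 0.002915416684171
  - 0.003237661202048
  - 0.003595459530278
  - 0.003992719380469
  - 0.004433774456046
  - 0.004923430071416
  - 0.005467013463911
  - 0.006070429235466
  - 0.00674022039043
  - 0.007483635464329
  - 0.008308702264743
  - 0.009224308768285
  - 0.010240291735295
  - 0.011367533613859
  - 0.012618068304434
  - 0.014005196341899
  - 0.015543610018937
  - 0.017249528917536
  - 0.019140846227384
  - 0.021237286102467
  - 0.023560572130188
  - 0.026134606748439
  - 0.028985661130545
  - 0.032142574648323
  - 0.03563696249899
  - 0.039503429418224
  - 0.043779786571522
  - 0.048507267687523
  - 0.053730739234964
  - 0.059498897910875
  - 0.065864446860866
  - 0.072884239851595
  - 0.080619380021803
  - 0.089135256818859
  - 0.098501501262393
  - 0.108791835765641
  - 0.12008379042152
  - 0.132458253004589
  - 0.145998815099909
  - 0.160790871985906
  - 0.176920429534065
  - 0.194472567965502
  - 0.213529510543143
  - 0.234168246136306
  - 0.256457659303755
  - 0.280455131629089
  - 0.306202595325545
  - 0.333722046659236
  - 1.0
onset:
  age:
  - 20
  - 21
  - 22
  - 23
  - 24
  - 25
  - 26
  - 27
  - 28
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  lambda:
  - 2.122268499821573e-05
  - 2.46247133130599e-05
  - 2.856605083954227e-05
  - 3.313010860669018e-05
  - 3.841248240250994e-05
  - 4.452248662089211e-05
  - 5.158479490860152e-05
  - 5.97411617660666e-05
  - 6.915218329985124e-05
  - 7.999903432858485e-05
  - 9.248509210885407e-05
  - 1.06837323321209e-04
  - 1.233072702616736e-04
  - 1.42171424761446e-04
  - 1.637307257481909e-04
  - 1.883088619399461e-04
  - 2.162490108841982e-04
  - 2.479086087376846e-04
  - 2.836517351085936e-04
  - 3.238387312872827e-04
  - 3.688127687412683e-04
  - 4.188832688991216e-04
  - 4.743063618965265e-04
  - 5.352629666824631e-04
  - 6.018355629025541e-04
  - 6.739852621263996e-04
  - 7.515312931749898e-04
  - 8.341353821439782e-04
  - 9.212936038129317e-04
  - 1.012337991732023e-03
  - 1.106449456289687e-03
  - 1.202682402106251e-03
  - 1.3e-03
  - 1.397317597893749e-03
  - 1.493550543710313e-03
  - 1.587662008267977e-03
  - 1.678706396187068e-03
  - 1.765864617856022e-03
  - 1.84846870682501e-03
  - 1.9260147378736e-03
  - 1.998164437097446e-03
  - 2.064737033317537e-03
  - 2.125693638103473e-03
  - 2.181116731100878e-03
  - 2.231187231258732e-03
  - 2.276161268712717e-03
  - 2.316348264891406e-03
  - 2.352091391262315e-03
  - 2.383750989115802e-03
  - 2.411691138060054e-03
  - 2.436269274251809e-03
  - 2.457828575238554e-03
  - 2.476692729738327e-03
  - 2.493162676678791e-03
  - 2.507514907891146e-03
  - 2.520000965671415e-03
  - 2.530847816700149e-03
  - 2.540258838233933e-03
  - 2.548415205091398e-03
  - 2.555477513379108e-03
  - 2.56158751759749e-03
  - 2.56686989139331e-03
  - 2.571433949160458e-03
  - 2.57537528668694e-03
  - 2.578777315001784e-03
  - 2.581712673397013e-03
  - 2.584244516121881e-03
  - 2.586427673196748e-03
  - 2.588309689781553e-03
  - 2.589931751054255e-03
  - 2.591329501000725e-03
  - 2.592533764195179e-03
  - 2.59357117979275e-03
  - 2.594464756738493e-03
  - 2.595234358749518e-03
  - 2.59589712704295e-03
  - 2.596467848128885e-03
  - 2.596959273310856e-03
  - 2.597382395867777e-03
  - 2.597746691251194e-03
  - 2.598060325032025e-03
natural_history:
  p_nonprogressive_dcis: 0.03
  dwell_rates:
    DCIS: 0.5
    T1a: 1.0
    T1b: 0.8
    T1c: 0.6
    T2plus: 0.0
  clinical_hazards:
    DCIS: 0.03
    T1a: 0.1
    T1b: 0.25
    T1c: 0.55
    T2plus: 1.2
survival:
  cure:
    DCIS:
      45-49: 0.97
      50-59: 0.96
      60-69: 0.95
      70plus: 0.94
    T1a:
      45-49: 0.92
      50-59: 0.91
      60-69: 0.9
      70plus: 0.88
    T1b:
      45-49: 0.86
      50-59: 0.85
      60-69: 0.83
      70plus: 0.8
    T1c:
      45-49: 0.7
      50-59: 0.68
      60-69: 0.66
      70plus: 0.62
    T2plus:
      45-49: 0.4
      50-59: 0.38
      60-69: 0.36
      70plus: 0.32
  ttd_mean:
    DCIS: 12.0
    T1a: 10.0
    T1b: 8.0
    T1c: 6.0
    T2plus: 4.0
  screen_benefit: 1.2
policy:
  sensitivity:
    DCIS: 0.726
    T1a: 0.785
    T1b: 0.656
    T1c: 0.78
    T2plus: 1.0
  referral:
    under50: 0.04
    over50: 0.034
  coverage:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  observed_coverage:
  - 0.543
  - 0.543
  - 0.65
  - 0.524
  - 0.488
  - 0.488

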