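# screensim country parameter bundle.
# Policy parameters (sensitivity, referral, observed coverage) are published
# programme values; natural-history, survival and demography parameters are
# SYNTHETIC stand-ins, not calibrated national estimates.

name: italy
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
  - 0.001199280287914
  - 0.001331964878727
  - 0.00147931840018
  - 0.001642960034197
  - 0.001824687097377
  - 0.002026494499798
  - 0.002250596296951
  - 0.002499449552303
  - 0.002775780748788
  - 0.003082615009828
  - 0.003423308414368
  - 0.003801583715739
  - 0.004221569800926
  - 0.004687845254773
  - 0.005205486422654
  - 0.005780120394621
  - 0.00641798336376
  - 0.007125984840423
  - 0.007911778231537
  - 0.008783838318803
  - 0.009751546189967
  - 0.01082528219116
  - 0.012016527473287
  - 0.013337974698047
  - 0.014803648445527
  - 0.01642903582032
  - 0.018231227680475
  - 0.020229070805764
  - 0.022443331169344
  - 0.024896868268633
  - 0.027614820193613
  - 0.030624798747517
  - 0.033957093466911
  - 0.037644882793003
  - 0.041724449897588
  - 0.04623539973558
  - 0.051220872748005
  - 0.056727749237558
  - 0.062806836743624
  - 0.069513030713674
  - 0.07690543636274
  - 0.085047436795987
  - 0.094006689214197
  - 0.103855027317799
  - 0.114668243887952
  - 0.126525723009033
  - 0.139509886619382
  - 0.153705415229919
  - 0.169198198035125
  - 0.186073963700761
  - 0.204416540469837
  - 0.224305693724276
  - 0.24581449187441
  - 0.26900615880941
  - 0.293930384813538
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
  - 3.265028461263959e-05
  - 3.788417432778446e-05
  - 4.394777052237272e-05
  - 5.096939785644643e-05
  - 5.909612677309222e-05
  - 6.849613326291095e-05
  - 7.936122293631004e-05
  - 9.190947964010246e-05
  - 1.063879743074635e-04
  - 1.230754374285921e-04
  - 1.422847570905447e-04
  - 1.643651128018601e-04
  - 1.897034927102671e-04
  - 2.18725268863763e-04
  - 2.51893424227986e-04
  - 2.897059414460709e-04
  - 3.326907859756895e-04
  - 3.81397859596438e-04
  - 4.363872847824517e-04
  - 4.982134327496658e-04
  - 5.674042596019512e-04
  - 6.44435798306341e-04
  - 7.297020952254255e-04
  - 8.234814872037895e-04
  - 9.259008660039295e-04
  - 1.036900403271384e-03
  - 1.156201989499984e-03
  - 1.283285203298428e-03
  - 1.417374775096818e-03
  - 1.557443064203112e-03
  - 1.702229932753364e-03
  - 1.850280618625002e-03
  - 2.0e-03
  - 2.149719381374998e-03
  - 2.297770067246636e-03
  - 2.442556935796888e-03
  - 2.582625224903182e-03
  - 2.716714796701572e-03
  - 2.843798010500016e-03
  - 2.963099596728616e-03
  - 3.074099133996071e-03
  - 3.17651851279621e-03
  - 3.270297904774574e-03
  - 3.355564201693659e-03
  - 3.432595740398049e-03
  - 3.501786567250334e-03
  - 3.563612715217549e-03
  - 3.618602140403562e-03
  - 3.667309214024311e-03
  - 3.710294058553929e-03
  - 3.748106575772014e-03
  - 3.781274731136237e-03
  - 3.810296507289733e-03
  - 3.83563488719814e-03
  - 3.857715242909455e-03
  - 3.876924562571408e-03
  - 3.893612025692536e-03
  - 3.908090520359897e-03
  - 3.92063877706369e-03
  - 3.931503866737089e-03
  - 3.940903873226908e-03
  - 3.949030602143554e-03
  - 3.956052229477628e-03
  - 3.962115825672215e-03
  - 3.967349715387361e-03
  - 3.971865651380019e-03
  - 3.975760794033664e-03
  - 3.979119497225766e-03
  - 3.982014907356235e-03
  - 3.984510386237316e-03
  - 3.986660770770347e-03
  - 3.988513483377198e-03
  - 3.990109507373461e-03
  - 3.991484241136143e-03
  - 3.992668244230029e-03
  - 3.993687887758385e-03
  - 3.994565920198285e-03
  - 3.995321958939778e-03
  - 3.995972916719658e-03
  - 3.996533371155683e-03
  - 3.997015884664654e-03
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
    DCIS: 0.821
    T1a: 1.0
    T1b: 0.717
    T1c: 0.814
    T2plus: 1.0
  referral:
    under50: 0.065
    over50: 0.058
  coverage:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  observed_coverage:
  - 0.596
  - 0.596
  - 0.632
  - 0.639
  - 0.615
  - 0.615

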