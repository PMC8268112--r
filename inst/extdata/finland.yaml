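# screensim country parameter bundle.
# Policy parameters (sensitivity, referral, observed coverage) are published
# programme values; natural-history, survival and demography parameters are
# SYNTHETIC stand-ins, not calibrated national estimates.

name: finland
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
  - 0.001299155366048
  - 0.001442881837064
  - 0.001602496107672
  - 0.001779751464964
  - 0.001976593982462
  - 0.002195183555583
  - 0.002437917194201
  - 0.002707454805536
  - 0.003006747722534
  - 0.003339070256383
  - 0.003708054576865
  - 0.004117729250598
  - 0.004572561795003
  - 0.005077505634514
  - 0.00563805187505
  - 0.006260286342398
  - 0.006950952359441
  - 0.007717519765054
  - 0.008568260702991
  - 0.009512332730568
  - 0.010559869812592
  - 0.011722081773295
  - 0.013011362774918
  - 0.014441409372246
  - 0.016027348652981
  - 0.017785876908402
  - 0.019735409180099
  - 0.021896239887662
  - 0.02429071454841
  - 0.026943412340439
  - 0.029881338919028
  - 0.033134128455245
  - 0.03673425330292
  - 0.040717238990681
  - 0.045121881350721
  - 0.049990461502584
  - 0.055368953072333
  - 0.061307214405709
  - 0.067859156587202
  - 0.075082875764485
  - 0.083040735561628
  - 0.091799382215282
  - 0.101429671470271
  - 0.112006482233495
  - 0.12360838755271
  - 0.136317148757696
  - 0.150216993747876
  - 0.165393635705907
  - 0.181932984367173
  - 0.199919498956547
  - 0.219434130801936
  - 0.240551805484402
  - 0.263338400504359
  - 0.287847186447289
  - 0.314114719415457
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
  - 2.285519922884771e-05
  - 2.651892202944912e-05
  - 3.07634393656609e-05
  - 3.56785784995125e-05
  - 4.136728874116456e-05
  - 4.794729328403766e-05
  - 5.555285605541702e-05
  - 6.433663574807172e-05
  - 7.447158201522443e-05
  - 8.615280620001446e-05
  - 9.95993299633813e-05
  - 1.15055578961302e-04
  - 1.32792444897187e-04
  - 1.531076882046341e-04
  - 1.763253969595902e-04
  - 2.027941590122496e-04
  - 2.328835501829826e-04
  - 2.669785017175066e-04
  - 3.054710993477162e-04
  - 3.487494029247661e-04
  - 3.971829817213659e-04
  - 4.511050588144387e-04
  - 5.107914666577978e-04
  - 5.764370410426526e-04
  - 6.481306062027507e-04
  - 7.258302822899688e-04
  - 8.093413926499889e-04
  - 8.982996423088996e-04
  - 9.921623425677728e-04
  - 1.090210144942178e-03
  - 1.191560952927355e-03
  - 1.295196433037501e-03
  - 1.4e-03
  - 1.504803566962499e-03
  - 1.608439047072645e-03
  - 1.709789855057822e-03
  - 1.807837657432227e-03
  - 1.9017003576911e-03
  - 1.990658607350011e-03
  - 2.074169717710031e-03
  - 2.151869393797249e-03
  - 2.223562958957347e-03
  - 2.289208533342202e-03
  - 2.348894941185561e-03
  - 2.402817018278634e-03
  - 2.451250597075234e-03
  - 2.494528900652284e-03
  - 2.533021498282494e-03
  - 2.567116449817017e-03
  - 2.59720584098775e-03
  - 2.62367460304041e-03
  - 2.646892311795366e-03
  - 2.667207555102813e-03
  - 2.684944421038698e-03
  - 2.700400670036619e-03
  - 2.713847193799986e-03
  - 2.725528417984775e-03
  - 2.735663364251928e-03
  - 2.744447143944583e-03
  - 2.752052706715962e-03
  - 2.758632711258835e-03
  - 2.764321421500487e-03
  - 2.769236560634339e-03
  - 2.773481077970551e-03
  - 2.777144800771152e-03
  - 2.780305955966014e-03
  - 2.783032555823564e-03
  - 2.785383648058037e-03
  - 2.787410435149365e-03
  - 2.789157270366121e-03
  - 2.790662539539243e-03
  - 2.791959438364039e-03
  - 2.793076655161423e-03
  - 2.7940389687953e-03
  - 2.79486777096102e-03
  - 2.79558152143087e-03
  - 2.796196144138799e-03
  - 2.796725371257844e-03
  - 2.79718104170376e-03
  - 2.797573359808978e-03
  - 2.797911119265258e-03
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
    DCIS: 0.596
    T1a: 0.811
    T1b: 0.761
    T1c: 0.946
    T2plus: 1.0
  referral:
    under50: 0.03
    over50: 0.028
  coverage:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  observed_coverage:
  - 0.85
  - 0.85
  - 0.859
  - 0.868
  - 0.73
  - 0.73

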