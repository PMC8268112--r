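# screensim country parameter bundle.
# Policy parameters (sensitivity, referral, observed coverage) are published
# programme values; natural-history, survival and demography parameters are
# SYNTHETIC stand-ins, not calibrated national estimates.

name: netherlands
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
  - 0.001249219075419
  - 0.001387424897853
  - 0.001540909153446
  - 0.001711358092577
  - 0.001900643429875
  - 0.002110842592215
  - 0.002344261142022
  - 0.00260345760131
  - 0.002891270923214
  - 0.003210850880749
  - 0.003565691666931
  - 0.003959669026335
  - 0.004397081265398
  - 0.00488269451717
  - 0.005421792665463
  - 0.00602023236298
  - 0.006684503607537
  - 0.007421796368984
  - 0.008240073786007
  - 0.00914815247517
  - 0.010155790512629
  - 0.011273783659698
  - 0.012514070404016
  - 0.0138898463749
  - 0.015415688660202
  - 0.01710769049702
  - 0.018983606723335
  - 0.021063010253652
  - 0.023367459669095
  - 0.025920677778922
  - 0.028748740701588
  - 0.031880276612002
  - 0.035346672787051
  - 0.03918228893001
  - 0.043424673938642
  - 0.048114782270271
  - 0.053297184815018
  - 0.059020267677357
  - 0.065336410445712
  - 0.072302133358641
  - 0.079978200214863
  - 0.08842966088974
  - 0.097725813891068
  - 0.107940065510822
  - 0.119149657836344
  - 0.131435233250641
  - 0.144880198218512
  - 0.159569844355442
  - 0.175590180361866
  - 0.193026424884553
  - 0.211961108442125
  - 0.232471733160838
  - 0.254627943418705
  - 0.278488170094501
  - 0.304095727758202
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
  - 3.91803415351675e-05
  - 4.546100919334135e-05
  - 5.273732462684726e-05
  - 6.116327742773572e-05
  - 7.091535212771065e-05
  - 8.219535991549313e-05
  - 9.523346752357204e-05
  - 1.102913755681229e-04
  - 1.276655691689561e-04
  - 1.476905249143105e-04
  - 1.707417085086537e-04
  - 1.972381353622321e-04
  - 2.276441912523205e-04
  - 2.624703226365156e-04
  - 3.022721090735832e-04
  - 3.476471297352851e-04
  - 3.992289431708274e-04
  - 4.576774315157255e-04
  - 5.236647417389419e-04
  - 5.978561192995989e-04
  - 6.808851115223415e-04
  - 7.733229579676091e-04
  - 8.756425142705104e-04
  - 9.881777846445473e-04
  - 1.111081039204715e-03
  - 1.244280483925661e-03
  - 1.387442387399981e-03
  - 1.539942243958114e-03
  - 1.700849730116182e-03
  - 1.868931677043734e-03
  - 2.042675919304036e-03
  - 2.220336742350002e-03
  - 2.4e-03
  - 2.579663257649998e-03
  - 2.757324080695963e-03
  - 2.931068322956265e-03
  - 3.099150269883818e-03
  - 3.260057756041886e-03
  - 3.412557612600019e-03
  - 3.555719516074339e-03
  - 3.688918960795284e-03
  - 3.811822215355452e-03
  - 3.924357485729489e-03
  - 4.026677042032391e-03
  - 4.119114888477659e-03
  - 4.202143880700401e-03
  - 4.276335258261058e-03
  - 4.342322568484274e-03
  - 4.400771056829173e-03
  - 4.452352870264714e-03
  - 4.497727890926417e-03
  - 4.537529677363484e-03
  - 4.572355808747679e-03
  - 4.602761864637768e-03
  - 4.629258291491346e-03
  - 4.652309475085689e-03
  - 4.672334430831043e-03
  - 4.689708624431876e-03
  - 4.704766532476428e-03
  - 4.717804640084507e-03
  - 4.729084647872289e-03
  - 4.738836722572264e-03
  - 4.747262675373153e-03
  - 4.754538990806658e-03
  - 4.760819658464832e-03
  - 4.766238781656023e-03
  - 4.770912952840396e-03
  - 4.774943396670919e-03
  - 4.778417888827482e-03
  - 4.781412463484779e-03
  - 4.783992924924416e-03
  - 4.786216180052637e-03
  - 4.788131408848153e-03
  - 4.789781089363371e-03
  - 4.791201893076034e-03
  - 4.792425465310062e-03
  - 4.793479104237941e-03
  - 4.794386350727733e-03
  - 4.795167500063589e-03
  - 4.795840045386819e-03
  - 4.796419061597583e-03
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
    DCIS: 0.865
    T1a: 0.553
    T1b: 0.481
    T1c: 0.857
    T2plus: 1.0
  referral:
    under50: 0.03
    over50: 0.023
  coverage:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  observed_coverage:
  - 0.755
  - 0.755
  - 0.762
  - 0.763
  - 0.757
  - 0.701

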