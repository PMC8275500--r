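price_scenario: increased
os_profile:
  shape: 1.127
  rate: 0.002
utilities:
  u_sd: 0.771
  u_sd_ae_control: 0.666
  u_sd_ae_intervention: 0.687
  u_pd: 0.612
  ae_fraction:
    control: 0.05
    intervention: 0.12
  ae_window_cycles: 1.0
costs:
  lo_price_initial: 16000.0
  lo_price_increased: 90000.0
  lo_admin_per_injection: 1500.0
  lo_injection_cycles:
  - 0.0
  - 2.0
  - 4.0
  - 6.0
  olar_cycle_control: 3244.0
  olar_cycle_intervention: 982.0
  ae_cost:
    control: 1500.0
    intervention: 2500.0
  followup_visit_cost: 215.0
psa:
  'n': 10000.0
  seed: 1.0
life_table:
  age:
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
  - 101
  - 102
  - 103
  - 104
  - 105
  - 106
  - 107
  - 108
  - 109
  - 110
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
  - 101
  - 102
  - 103
  - 104
  - 105
  - 106
  - 107
  - 108
  - 109
  - 110
  sex:
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - male
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  - female
  annual_mortality:
  - 0.0038924
  - 0.0042439
  - 0.0046272
  - 0.0050449
  - 0.0055003
  - 0.0059966
  - 0.0065375
  - 0.0071271
  - 0.0077697
  - 0.0084699
  - 0.0092329
  - 0.0100644
  - 0.0109702
  - 0.0119572
  - 0.0130323
  - 0.0142034
  - 0.015479
  - 0.016868
  - 0.0183806
  - 0.0200274
  - 0.0218202
  - 0.0237714
  - 0.0258948
  - 0.0282051
  - 0.0307183
  - 0.0334515
  - 0.0364234
  - 0.0396538
  - 0.0431642
  - 0.0469777
  - 0.0511191
  - 0.0556147
  - 0.060493
  - 0.0657841
  - 0.0715201
  - 0.0777351
  - 0.0844652
  - 0.0917485
  - 0.0996249
  - 0.1081364
  - 0.1173266
  - 0.1272406
  - 0.137925
  - 0.1494275
  - 0.1617961
  - 0.1750792
  - 0.1893248
  - 0.2045794
  - 0.2208876
  - 0.238291
  - 0.2568268
  - 0.2765263
  - 0.2974142
  - 0.3195057
  - 0.3428057
  - 0.367306
  - 0.3929839
  - 0.4197995
  - 0.4476935
  - 0.4765859
  - 1.0
  - 0.0025966
  - 0.0028313
  - 0.0030872
  - 0.0033661
  - 0.0036702
  - 0.0040017
  - 0.0043631
  - 0.0047571
  - 0.0051865
  - 0.0056546
  - 0.0061648
  - 0.0067209
  - 0.0073269
  - 0.0079874
  - 0.0087072
  - 0.0094915
  - 0.0103461
  - 0.0112772
  - 0.0122916
  - 0.0133966
  - 0.0146002
  - 0.0159111
  - 0.0173386
  - 0.0188929
  - 0.0205852
  - 0.0224272
  - 0.0244321
  - 0.0266137
  - 0.0289872
  - 0.0315689
  - 0.0343765
  - 0.0374289
  - 0.0407466
  - 0.0443515
  - 0.0482673
  - 0.0525191
  - 0.0571342
  - 0.0621413
  - 0.0675713
  - 0.0734569
  - 0.0798329
  - 0.086736
  - 0.0942048
  - 0.10228
  - 0.111004
  - 0.120421
  - 0.1305767
  - 0.1415179
  - 0.1532925
  - 0.1659488
  - 0.179535
  - 0.1940988
  - 0.2096862
  - 0.2263409
  - 0.2441031
  - 0.2630085
  - 0.2830864
  - 0.3043586
  - 0.3268372
  - 0.3505232
  - 1.0
indirect_costs:
  age:
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
  - 101
  - 102
  - 103
  - 104
  - 105
  - 106
  - 107
  - 108
  - 109
  - 110
  annual_cost:
  - 2220.5678878
  - 2299.6638694
  - 2381.5772267
  - 2466.408314
  - 2554.2610599
  - 2645.2430951
  - 2739.4658838
  - 2837.0448609
  - 2938.0995727
  - 3042.7538239
  - 3151.1358291
  - 3263.3783697
  - 3379.6189569
  - 3500.0
  - 3624.6689808
  - 3753.7786344
  - 3887.4871362
  - 4025.958296
  - 4169.3617581
  - 4317.8732098
  - 4471.6745962
  - 4630.9543432
  - 4795.9075883
  - 4966.7364201
  - 5143.650125
  - 5326.8654447
  - 5516.6068406
  - 5713.1067698
  - 5916.6059693
  - 6127.353751
  - 6345.6083074
  - 6571.6370274
  - 6805.7168247
  - 7048.1344761
  - 7299.1869738
  - 7559.1818882
  - 7828.4377459
  - 8107.2844187
  - 8396.0635289
  - 8695.1288668
  - 9004.8468251
  - 9325.5968468
  - 9657.7718908
  - 10001.7789132
  - 10358.0393656
  - 10726.9897115
  - 11109.0819613
  - 11504.7842258
  - 11914.5812898
  - 12338.9752058
  - 12778.4859095
  - 13233.6518565
  - 13705.030682
  - 14193.199884
  - 14698.7575308
  - 15222.3229937
  - 15764.537706
  - 16326.0659485
  - 16907.5956634
  - 17509.8392974
  - 18133.5346743
  end_of_life_cost:
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
  - 25000.0
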