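"age","sex","annual_mortality"
50,"male",0.00389240487686815
51,"male",0.00424394904486869
52,"male",0.00462716926215279
53,"male",0.00504490576403571
54,"male",0.005500250817985
55,"male",0.00599657058825087
56,"male",0.00653752880206615
57,"male",0.00712711234741292
58,"male",0.00776965893801085
59,"male",0.00846988698624185
60,"male",0.00923292782892493
61,"male",0.0100643604539035
62,"male",0.0109702488769092
63,"male",0.0119571823176818
64,"male",0.0130323183212946
65,"male",0.0142034289644132
66,"male",0.0154789502760088
67,"male",0.0168680349869241
68,"male",0.0183806087015558
69,"male",0.0200274295564608
70,"male",0.0218201513933971
71,"male",0.0237713904263854
72,"male",0.0258947953217615
73,"male",0.0282051205344791
74,"male",0.0307183026503703
75,"male",0.033451539369528
76,"male",0.0364233706268717
77,"male",0.0396537611782826
78,"male",0.0431641837799634
79,"male",0.0469777018499673
80,"male",0.0511190502187672
81,"male",0.0556147122445938
82,"male",0.060492991183021
83,"male",0.0657840732528651
84,"male",0.0715200793259211
85,"male",0.0777351015809808
86,"male",0.0844652207985365
87,"male",0.0917484992288301
88,"male",0.0996249431422654
89,"male",0.108136428271139
90,"male",0.117326580383773
91,"male",0.127240602211992
92,"male",0.137925036905056
93,"male",0.149427457144156
94,"male",0.161796068072527
95,"male",0.175079211346918
96,"male",0.189324756988431
97,"male",0.204579369423038
98,"male",0.220887634302996
99,"male",0.238291033572713
100,"male",0.256826758004851
101,"male",0.276526349339744
102,"male",0.297414168501325
103,"male",0.319505692447976
104,"male",0.342805650368134
105,"male",0.367306020452548
106,"male",0.392983921618018
107,"male",0.419799450464275
108,"male",0.44769353238242
109,"male",0.476585876800321
110,"male",1
50,"female",0.00259662292743024
51,"female",0.00283130438106505
52,"female",0.00308716337989223
53,"female",0.00336610476586496
54,"female",0.00367020353996528
55,"female",0.00400171984004283
56,"female",0.00436311519475463
57,"female",0.0047570701542069
58,"female",0.00518650340423321
59,"female",0.00565459247763189
60,"female",0.00616479618205035
61,"female",0.00672087887043504
62,"female",0.00732693668590567
63,"female",0.00798742591840751
64,"female",0.00870719361530659
65,"female",0.00949151059196163
66,"female",0.0103461069909044
67,"female",0.0112772105391757
68,"female",0.0122915876521346
69,"female",0.0133965875280792
70,"female",0.0146001893706121
71,"female",0.0159110528640131
72,"female",0.0173385720099587
73,"female",0.018892932410606
74,"female",0.0205851720519415
75,"female",0.0224272456008064
76,"female",0.0244320921772591
77,"female",0.0266137064987607
78,"female",0.0289872132115665
79,"female",0.0315689441247847
80,"female",0.0343765179405727
81,"female",0.0374289219261402
82,"female",0.040746594795475
83,"female",0.044351509856374
84,"female",0.0482672572263599
85,"female",0.0525191236239192
86,"female",0.0571341678933602
87,"female",0.0621412900164157
88,"female",0.067571290895427
89,"female",0.0734569196557273
90,"female",0.0798329046035234
91,"female",0.0867359632862081
92,"female",0.0942047863325643
93,"female",0.102279988901614
94,"female",0.111004022645854
95,"female",0.120421040107927
96,"female",0.13057670243758
97,"female",0.141517920266147
98,"female",0.153292516549612
99,"female",0.16594879924523
100,"female",0.179535030897165
101,"female",0.194098781673514
102,"female",0.209686152248146
103,"female",0.226340853315179
104,"female",0.244103129655687
105,"female",0.263008518775838
106,"female",0.28308643746911
107,"female",0.304358594519526
108,"female",0.326837234475083
109,"female",0.350523226299885
110,"female",1
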