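"age","annual_cost","end_of_life_cost"
50,2220.5678878188,25000
51,2299.6638693527,25000
52,2381.57722671606,25000
53,2466.4083140155,25000
54,2554.2610599417,25000
55,2645.24309509504,25000
56,2739.46588384654,25000
57,2837.04486089565,25000
58,2938.09957269223,25000
59,3042.75382389582,25000
60,3151.13582905193,25000
61,3263.37836967082,25000
62,3379.61895690148,25000
63,3500,25000
64,3624.66898079868,25000
65,3753.77863438976,25000
66,3887.48713624497,25000
67,4025.9582960003,25000
68,4169.36175814325,25000
69,4317.8732098486,25000
70,4471.6745962171,25000
71,4630.95434318103,25000
72,4795.90758834949,25000
73,4966.7364200764,25000
74,5143.65012504401,25000
75,5326.86544466522,25000
76,5516.60684061897,25000
77,5713.10676984383,25000
78,5916.60596932682,25000
79,6127.35375103635,25000
80,6345.60830736055,25000
81,6571.6370274252,25000
82,6805.71682467891,25000
83,7048.13447614667,25000
84,7299.1869737676,25000
85,7559.1818882472,25000
86,7828.43774586995,25000
87,8107.28441873382,25000
88,8396.06352888484,25000
89,8695.12886684686,25000
90,9004.84682505914,25000
91,9325.59684675296,25000
92,9657.77189081699,25000
93,10001.7789132211,25000
94,10358.0393655882,25000
95,10726.9897115255,25000
96,11109.0819613466,25000
97,11504.7842258409,25000
98,11914.5812897679,25000
99,12338.9752057788,25000
100,12778.4859094945,25000
101,13233.6518564907,25000
102,13705.0306819745,25000
103,14193.1998839564,25000
104,14698.7575307577,25000
105,15222.3229937196,25000
106,15764.5377060097,25000
107,16326.0659484584,25000
108,16907.595663386,25000
109,17509.8392974176,25000
110,18133.5346743198,25000
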