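time_to_onset,truncation_time
90.067560596362355,410.95352462818863
102.09769634577516,157.72981550521223
125.66171643578362,132.63310126843868
65.0573958916941,423.10589827550592
383.17855429061763,415.23309528548288
80.84403683395027,246.56429837597545
141.19136410940209,381.15640157228353
205.10656602082148,227.84285506024034
385.17684436573597,498.64864182565384
207.98812885068435,454.65534760546888
97.122961650135636,160.41557228122844
283.88373506099867,298.30242058215674
419.02141583556516,427.33883368666301
178.21814722936395,456.52208642731438
265.5310459302757,468.75483604753413
32.479482471262557,333.07082666037621
51.828125778743619,232.1418979924639
139.12827080172696,446.12698644259962
126.39546935486304,401.41162931360321
157.81766816702296,412.05425761151145
319.81034831845562,430.49463720736111
210.64561476534683,456.47869442543032
79.099843830778525,262.16176031902444
157.28716432049876,457.58124769991281
187.84307005896531,315.96188985113997
209.07487459808468,432.06359442719275
28.423741989856651,438.98897829977813
17.186762501277681,161.95576892537071
202.80299037269177,474.64819402922899
10.365316244904829,384.42226576665433
70.638631118158784,123.81090688123373
197.87784318241853,284.46584738837566
22.396916117114589,372.21658107638376
104.55588639496339,340.93915386986936
59.646895887884874,161.86958708707249
91.382864313633434,163.49515512795193
171.71573204853726,335.70900177187303
29.041497084267185,102.51114276563753
93.363394580698056,392.61772155389207
73.080333137581903,395.7219080762008
24.541424534748526,163.34587536426267
51.169611814071608,68.363825844600825
72.143804965817267,121.99174307286745
81.2024822459029,257.44681602111098
93.684071921686609,152.54272150225012
141.70017838442092,243.0512981566136
144.33466389410341,239.39579853951011
16.457139442313842,403.54473342606815
243.97351413601589,388.63869908498617
216.23883358317335,489.22602096921787
230.32538611804145,317.99146916857001
199.27519251274035,258.71778089948941
173.71053314445601,326.72325251810264
293.94631877717268,477.62934382166736
75.847028568536828,112.13890621112664
167.71281548999707,245.00479339272727
197.98345236421741,245.42401756881748
90.502938309305136,187.79937920742677
11.765087634079444,76.830213477369426
56.679268597274842,72.379624501103564
64.823658453180471,171.12437522644186
130.80121728266775,304.25875184382323
251.50888899352296,410.30941412714327
103.02191268543832,222.96565642044888
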