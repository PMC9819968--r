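city,year,croplands,forests,grazing_lands,fishing_grounds,built_up
Chengdu,2000,1,1,10.91,2.49,1
Deyang,2000,1,1,14.63,2.23,1
Mianyang,2000,1,1,1.09,1.78,1
Suining,2000,1,1,28.39,1.32,1
Leshan,2000,1,1,2.10,1.02,1
Meishan,2000,1,1.04,15.84,3.51,1
Yaan,2000,1,1,1,1,1
Ziyang,2000,1,2.80,29.12,1.93,1
Chengdu,2019,1,2.75,13.27,7.12,1
Deyang,2019,1,1.18,15.88,6.26,1
Mianyang,2019,1,1,1.41,5.34,1
Suining,2019,1,1,35.86,4.11,1
Leshan,2019,1,1,2.80,5.08,1
Meishan,2019,1,3.87,18.74,10.23,1
Yaan,2019,1,1,1,1,1
Ziyang,2019,1,9.06,40.85,4.93,1
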