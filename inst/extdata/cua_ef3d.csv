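city,year,ef3d_per_capita
Chengdu,2000,4.99
Chengdu,2010,6.24
Chengdu,2015,4.73
Chengdu,2019,4.57
Deyang,2000,9.50
Deyang,2010,13.97
Deyang,2015,13.71
Deyang,2019,14.33
Mianyang,2000,2.53
Mianyang,2010,4.78
Mianyang,2015,4.61
Mianyang,2019,5.39
Suining,2000,10.90
Suining,2010,23.66
Suining,2015,19.77
Suining,2019,18.83
Leshan,2000,1.84
Leshan,2010,3.29
Leshan,2015,3.65
Leshan,2019,4.18
Meishan,2000,8.10
Meishan,2010,12.64
Meishan,2015,18.17
Meishan,2019,15.30
Yaan,2000,1.43
Yaan,2010,2.33
Yaan,2015,2.41
Yaan,2019,2.38
Ziyang,2000,11.02
Ziyang,2010,24.10
Ziyang,2015,35.19
Ziyang,2019,38.76
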