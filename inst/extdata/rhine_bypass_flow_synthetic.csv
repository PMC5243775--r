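"station_index","distance_m","position","velocity_m_s"
1,0,"near_bottom",0.31
2,6,"near_bottom",0.36
3,12,"near_bottom",0.42
4,18,"near_bottom",0.46
5,24,"near_bottom",0.5
6,30,"near_bottom",0.48
7,36,"near_bottom",0.44
8,42,"near_bottom",0.41
9,48,"near_bottom",0.38
10,54,"near_bottom",0.34
11,60,"near_bottom",0.3
1,0,"center",0.85
2,6,"center",0.95
3,12,"center",1.1
4,18,"center",1.25
5,24,"center",1.4
6,30,"center",1.32
7,36,"center",1.2
8,42,"center",1.1
9,48,"center",1.02
10,54,"center",0.94
11,60,"center",0.88
1,0,"near_shore",0.08
2,6,"near_shore",0.1
3,12,"near_shore",0.12
4,18,"near_shore",0.14
5,24,"near_shore",0.16
6,30,"near_shore",0.15
7,36,"near_shore",0.13
8,42,"near_shore",0.12
9,48,"near_shore",0.1
10,54,"near_shore",0.09
11,60,"near_shore",0.08
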