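# Electron collision stopping power of liquid water (rho = 1 g/cm^3).
# Transcribed approximately from standard reference compilations; the
# sub-keV rows extend the reference grid through the stopping-power peak and
# are approximate. energy in keV, stopping power in keV/um.
energy_keV	stopping_keV_per_um
0.1	20.0
0.2	24.0
0.3	23.0
0.5	19.5
0.7	16.0
1	12.62
1.5	9.70
2	7.76
3	5.80
4	4.73
5	3.97
7	3.04
10	2.256
15	1.647
20	1.317
30	0.9653
40	0.7777
50	0.6603
70	0.5212
100	0.4115
150	0.3238
200	0.2793
300	0.2355
400	0.2148
500	0.2034
700	0.1920
1000	0.1849
1500	0.1822
2000	0.1824
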