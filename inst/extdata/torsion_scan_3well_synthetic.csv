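"angle_deg","energy_kcal"
0,0.317321
10,0.440097
20,0.773115
30,1.247846
40,1.745226
50,2.1166
60,2.234641
70,2.049606
80,1.613891
90,1.057321
100,0.53075
110,0.155035
120,0
130,0.088041
140,0.399415
150,0.866795
160,1.371526
170,1.764544
180,1.917321
190,1.778225
200,1.397238
210,0.901436
220,0.438808
230,0.127434
240,0.034641
250,0.180747
260,0.544431
270,1.057321
280,1.60021
290,2.023894
300,2.2
310,2.077207
320,1.705833
330,1.213205
340,0.747403
350,0.426416
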