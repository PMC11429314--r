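BW,GEZI,EGP,CI,SI,tau1,tau2,p2,VG
89,3.87e-8,1.4,2010,4.93e-4,49,47,1.06e-2,253
89,2.20e-3,1.33,2010,8.11e-4,49,47,1.06e-2,253
63,4.38e-3,0.6,1281,9.64e-5,41,10,1.16e-2,261
65,3.50e-3,0.856,909,1.70e-4,71,70,2.33e-2,199
65,1.64e-3,1.07,909,4.63e-4,71,70,2.33e-2,199
116,7.58e-8,2.59,1813,3.77e-4,91,70,8.14e-3,337
116,1.64e-5,0.98,1813,3.77e-4,91,70,8.14e-3,337
64,4.33e-3,0.6,1535,2.05e-4,46,46,9.63e-3,188
51,1.01e-3,0.603,588,4.12e-4,68,30,9.15e-3,104
77,2.30e-3,1.11,1806,8.16e-4,60,60,1.01e-2,263
65,1.00e-8,1.3,540,3.68e-4,95,37,1.03e-2,137
100,6.39e-3,1.27,875,2.56e-4,131,21,1.03e-2,193
64,1.04e-3,0.611,1309,6.03e-4,53,53,1.02e-2,204
51,3.79e-3,0.603,588,9.48e-4,68,30,9.15e-3,104
65,1.00e-8,0.601,540,5.40e-4,95,37,1.03e-2,137
100,6.39e-3,3.45,875,6.89e-4,131,21,1.03e-2,193
64,1.04e-3,0.611,1309,1.73e-3,53,53,1.02e-2,204
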