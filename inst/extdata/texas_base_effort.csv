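season,bay,trips,harvest_red_drum,harvest_seatrout
high,GL,191165,30997,104042
high,MG,75973,13471,54118
high,SA,57864,14321,28796
high,AR,92666,14930,20811
high,CC,62542,13898,20298
high,UL,83636,19488,76372
high,LL,68104,17097,56830
low,GL,50761,7243,17865
low,MG,29020,5575,10406
low,SA,19232,5035,12892
low,AR,52620,8461,16045
low,CC,35516,5655,6746
low,UL,40916,4143,18537
low,LL,33185,6050,15154
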