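t,ti,to,tih,RH,RHout,dp,SAF,NH3,CO2,CO,H2S
0,22,5,26,70,60,25,0.25,0,500,0,0
240,22,15,22,70,60,25,0.25,0,500,0,0
480,26,15,30,70,60,25,0.25,0,500,0,0
840,25,15,30,70,60,25,0.25,0,500,0,0
1140,25,15,25,70,60,25,0.25,0,2500,0,0
1440,24.5,15,25,70,60,25,0.25,0,3500,0,0
1620,25,15,25,70,60,25,0.25,0,500,0,0
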