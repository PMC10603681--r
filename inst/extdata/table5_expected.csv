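t_start,t_end,kind,name,match
0,5,mode,mode,^M1$
0,5,alert,m1_entry,22
0,5,actuator,heater,^100$
0,5,actuator,blind_pos,^2$
0,5,actuator,vent_power,^25$
25,40,actuator,vent_power,^0$
25,40,actuator,blind_pos,^0$
25,40,actuator,circ_fan,^1$
295,310,actuator,circ_fan,^0$
295,310,actuator,blind_pos,^3$
295,310,actuator,vent_power,^35$
595,610,mode,mode,^TR$
595,610,actuator,heater,^0$
595,610,actuator,blind_pos,^4$
895,910,mode,mode,^M2$
895,910,actuator,heater,^10$
895,910,actuator,blind_pos,^3$
1195,1210,actuator,blind_pos,^4$
1495,1510,mode,emergency,^1$
1495,1510,alert,gas_exceed,CO2
1495,1510,actuator,heater,^50$
1495,1510,actuator,blind_pos,^4$
1675,1690,mode,emergency,^0$
1675,1690,actuator,heater,^10$
1675,1690,actuator,blind_pos,^3$
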