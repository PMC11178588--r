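name,half_life_value,half_life_unit,alpha_energies,gamma_probability,photopeak_kev,parents,reference
Ac-225,9.92,d,5.8:1.0,0,NA,NA,NDS/NuDat evaluated data
Fr-221,4.8,min,6.3:1.0,0.114,218,Ac-225:1.0,NDS/NuDat evaluated data
At-217,32,ms,7.1:1.0,0,NA,Fr-221:1.0,NDS/NuDat evaluated data
Bi-213,45.6,min,5.9:0.022,0.259,440,At-217:1.0,NDS/NuDat evaluated data
Po-213,3.72,us,8.4:1.0,0,NA,Bi-213:0.978,NDS/NuDat evaluated data
Tl-209,2.16,min,,0,NA,Bi-213:0.022,NDS/NuDat evaluated data
Pb-209,3.23,h,,0,NA,Po-213:1.0;Tl-209:1.0,NDS/NuDat evaluated data
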