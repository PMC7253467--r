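group,rt_um,rt_sd_um,fd_um,fd_sd_um,irlt_um,irlt_sd_um,fda,fda_sd
C,185,10,121,15,8,2,13,3
PG1,180,27,119,6,5,1,21,4
PG2,218,19,78,38,23,12,5,2
PG3,322,13,12,20,84,5,2,0
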