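variant,pH,Kd_uM,Kd_err_uM,T_K
WT,7,105,15,300
WT,6,800,150,300
H294A,7,35,15,300
H294A,6,125,5,300
E261D,7,108,11,300
E261D,6,742,141,300
WT_remeasured,7,113,14,300
WT_remeasured,6,802,150,300
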