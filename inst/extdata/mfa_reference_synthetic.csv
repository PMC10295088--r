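reaction_id,reference_flux,direction_sign
EX_glc,-100,1
EX_co2,160,1
EX_ac,55,1
EX_o2,140,1
GLY,85,1
PPP,15,1
PDH,70,1
TCA1,30,1
TCA2,28,1
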