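subject,behavior,start_s,stop_s
female1,active_swimming,0,420
female1,active_swimming,500,3600
male1,active_swimming,0,3600
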