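subject_id,strand,step_index,step_label,sv_ref,sv_probe
A,no_tourniquet,1,baseline,100,100
A,no_tourniquet,2,LBNP1,80,70
B,no_tourniquet,1,baseline,90,90
B,no_tourniquet,2,LBNP1,54,63
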