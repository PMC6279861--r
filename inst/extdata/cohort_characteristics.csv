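characteristic,case_pos,case_neg,control_pos,control_neg
female,23,28,22,29
hypertension,41,10,33,18
diabetes,25,26,16,35
hyperlipidemia,18,33,12,39
smoking,22,29,17,34
drinking,14,37,16,35
atrial_fibrillation,13,38,10,41
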