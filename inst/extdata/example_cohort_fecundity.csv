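# agestagelt 0.1.0
id,age_day,eggs
F01,12,48
F01,13,60
F01,15,22
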