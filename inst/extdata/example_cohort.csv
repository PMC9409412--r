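# agestagelt 0.1.0
# strain_label=example
# stage_order=egg|larva|pupa|female|male
# n0=3
id,sex,fate,death_stage,emergence_day,death_day,dur_egg,dur_larva,dur_pupa
F01,female,died_adult,female,12,25,3,5,4
M01,male,died_adult,male,13,28,3,6,4
U01,unknown,died_preadult,larva,NA,6,3,NA,NA
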