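b8c0f4661ae05e0db019cfaeac556c20  character_definitions.csv
a7f5658c7236cf32d2275d57323aa271  coelodonta_c7.csv
8d3f5cd3272394274ee75d6b90481ac3  extant_rhino.csv
13c6ea85741c422525fba5c8ddf7cbe7  table4_matrix.csv
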