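"file","md5"
"table1_pearson.csv","23048a6fede6c67849eb4d7efde928b3"
"table2_contributions.csv","60c64bd20f20f7c48d4231c2a16eea51"
"table3_contributions.csv","0db059a9d316dd5d522647939302929d"
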