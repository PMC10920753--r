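"country","unit","threshold_fish"
"Norlandia","co-1",150000
"Norlandia","co-2",250000
"Norlandia","co-3",2e+05
"Yearvia","co-1",3e+05
"Yearvia","co-2",5e+05
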