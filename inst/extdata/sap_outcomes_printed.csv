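group,survivors,deaths,group_size
control,45,5,50
observation,50,1,50
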