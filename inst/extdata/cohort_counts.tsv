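sample	n_female	n_male
full	27819	19372
sibling	9267	6145
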