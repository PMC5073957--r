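polarity	domain	n_terminal	interdomain	c_terminal
positive	97	10	14	5
negative	85	29	34	46
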