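X	activates	X
X	inhibits	Y
Y	inhibits	X
Y	activates	Y
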