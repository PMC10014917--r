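gene	major	function
CYP2C19	*1	normal
CYP2C19	*2	no_function
CYP2C19	*3	no_function
CYP2C19	*11	normal
CYP2C19	*17	increased
CYP2C19	*38	normal
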