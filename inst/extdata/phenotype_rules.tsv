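function_a	function_b	CPIC	DPWG
no_function	no_function	PM	PM
no_function	decreased	IM	IM
no_function	normal	IM	IM
no_function	increased	IM	IM
decreased	decreased	IM	IM
decreased	normal	IM	IM
decreased	increased	NM	NM
normal	normal	NM	NM
normal	increased	RM	NM
increased	increased	UM	UM
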