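metabolite	from	to	score	proteins	reversible
L-Pipecolate	C	X	3		TRUE
H2O2	X	C	2		TRUE
GM3	C	L	1		TRUE
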