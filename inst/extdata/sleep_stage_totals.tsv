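class	total
Awake	8285
N1	2804
N2	17799
N3	5703
REM	7717
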