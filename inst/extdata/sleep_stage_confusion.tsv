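class	Awake	N1	N2	N3	REM
Awake	7270	235	349	79	352
N1	55	2572	75	4	98
N2	278	269	15418	396	1438
N3	69	2	506	5126	0
REM	183	195	186	10	7143
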