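target	kind	sample	statistic	numerator	denominator
t1	percentage	Petrosia ficiformis	arrays with assigned taxonomy / validated arrays	53	77
t2	percentage	Sarcotragus foetidus	arrays with assigned taxonomy / validated arrays	40	47
t3	percentage	Aplysina aerophoba	arrays with assigned taxonomy / validated arrays	240	283
t4	percentage	Sarcotragus foetidus	repeats matching known repeat references / distinct repeats	25	40
t5	percentage	Petrosia ficiformis	repeats assigned to a structural superclass / distinct repeats	47	67
t6	percentage	Sarcotragus foetidus	repeats assigned to a structural superclass / distinct repeats	21	40
t7	coverage_quotient	seawater	mapped basepairs / assembly basepairs	3642606507	216407276
t8	coverage_quotient	Sarcotragus foetidus	mapped basepairs / assembly basepairs	5378691619	190159175
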