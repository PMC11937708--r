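category	code
fever_neutropenia	D709C
fever_neutropenia	R502
fever_neutropenia	R508
fever_neutropenia	R509
gastroenteritis_colitis	K521
gastroenteritis_colitis	A047
anemia	D649
anemia	D630
urinary_tract_infection	N390
urinary_problems	R339
urinary_problems	R301
urinary_problems	N390X
urinary_problems	N304
urinary_problems	N109
urinary_problems	T830
urinary_problems	R391
urinary_problems	R319
urinary_problems	N300
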