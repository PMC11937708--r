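dimension	level	decrement
anchor	-	0.97
any_dysfunction	-	0.02
any_level3	-	0.05
mobility	2	0.04
mobility	3	0.16
self_care	2	0.05
self_care	3	0.11
usual_activities	2	0.02
usual_activities	3	0.05
pain_discomfort	2	0.06
pain_discomfort	3	0.20
anxiety_depression	2	0.04
anxiety_depression	3	0.12
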