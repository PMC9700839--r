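channel	126	127N	128N	129N	130N	131N	132N	133N	134N
126	0.95	0.05	0	0	0	0	0	0	0
127N	0.05	0.9	0.05	0	0	0	0	0	0
128N	0	0.05	0.9	0.05	0	0	0	0	0
129N	0	0	0.05	0.9	0.05	0	0	0	0
130N	0	0	0	0.05	0.9	0.05	0	0	0
131N	0	0	0	0	0.05	0.9	0.05	0	0
132N	0	0	0	0	0	0.05	0.9	0.05	0
133N	0	0	0	0	0	0	0.05	0.9	0.05
134N	0	0	0	0	0	0	0	0.05	0.95
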