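label	role	expected_amount	plex
126	standard	1	TMTPro
127N	standard	5	TMTPro
128N	standard	10	TMTPro
129N	standard	1	TMTPro
130N	standard	5	TMTPro
131N	standard	10	TMTPro
132N	standard	1	TMTPro
133N	standard	5	TMTPro
134N	standard	10	TMTPro
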