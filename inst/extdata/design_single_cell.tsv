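label	role	expected_amount	plex
126	blank	0	TMTPro
127N	single_cell	1	TMTPro
128N	single_cell	1	TMTPro
129N	single_cell	1	TMTPro
130N	single_cell	1	TMTPro
131N	single_cell	1	TMTPro
132N	single_cell	1	TMTPro
133N	single_cell	1	TMTPro
134N	carrier	250	TMTPro
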