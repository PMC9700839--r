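label	composition	plex
126	C8H16N	TMT11
127N	C8H16[15N]	TMT11
127C	C7[13C]1H16N	TMT11
128N	C7[13C]1H16[15N]	TMT11
128C	C6[13C]2H16N	TMT11
129N	C6[13C]2H16[15N]	TMT11
129C	C5[13C]3H16N	TMT11
130N	C5[13C]3H16[15N]	TMT11
130C	C4[13C]4H16N	TMT11
131N	C4[13C]4H16[15N]	TMT11
131C	C3[13C]5H16N	TMT11
126	C8H16N	TMTPro
127N	C8H16[15N]	TMTPro
127C	C7[13C]1H16N	TMTPro
128N	C7[13C]1H16[15N]	TMTPro
128C	C6[13C]2H16N	TMTPro
129N	C6[13C]2H16[15N]	TMTPro
129C	C5[13C]3H16N	TMTPro
130N	C5[13C]3H16[15N]	TMTPro
130C	C4[13C]4H16N	TMTPro
131N	C4[13C]4H16[15N]	TMTPro
131C	C3[13C]5H16N	TMTPro
132N	C3[13C]5H16[15N]	TMTPro
132C	C2[13C]6H16N	TMTPro
133N	C2[13C]6H16[15N]	TMTPro
133C	C1[13C]7H16N	TMTPro
134N	C1[13C]7H16[15N]	TMTPro
134C	[13C]8H16N	TMTPro
135N	[13C]8H16[15N]	TMTPro
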