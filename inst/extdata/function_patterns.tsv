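# function<TAB>template<TAB>max_gap[<TAB>pmod_type]
# seeded with the published example patterns; additional entries below the
# marker are expert additions shipped as editable config
act	<Protein> activity	1
act	activity of <Protein>	1
act	activation of <Protein>	1
tscript	transcription of <Protein>	1
tscript	<Protein> transcription	1
tscript	transcriptional activation of <Protein>	1
complex	<Protein>/<Protein> complex	0
complex	complex of <Protein> and <Protein>	1
deg	<Protein> degradation	1
deg	degradation of <Protein>	1
pmod	phosphorylation of <Protein>	1	P
pmod	<Protein> phosphorylation	1	P
tloc	translocation of <Protein>	1
tloc	<Protein> translocation	1
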