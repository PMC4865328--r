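# relation verb lemmas: lemma<TAB>increases|decreases
# seeded from the regulation-trigger convention of the BioNLP shared tasks
# plus common causal verbs; editable config (the original expert list was
# never published)
stimulate	increases
induce	increases
increase	increases
enhance	increases
promote	increases
activate	increases
upregulate	increases
regulate	increases
mediate	increases
elevate	increases
augment	increases
trigger	increases
potentiate	increases
reduce	decreases
decrease	decreases
inhibit	decreases
suppress	decreases
downregulate	decreases
attenuate	decreases
block	decreases
impair	decreases
abolish	decreases
diminish	decreases
repress	decreases
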