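# polarity-flipping context keywords, one per line
inhibition
mutant
inactivation
knockout
knockdown
silencing
depletion
deficiency
loss
absence
blockade
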