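# Candidates removed when a phrase here occurs anywhere inside the surface
# (word-boundary substring match).
wild type
control group
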