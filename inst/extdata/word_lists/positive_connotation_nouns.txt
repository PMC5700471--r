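# Nouns denoting normal (non-pathological) concepts; a two-token candidate
# containing one of these cannot denote an abnormality by itself
# ("cognitive development" vs "cognitive development impairment").
development
growth
function
ability
intelligence
coordination
behaviour
behavior
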