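# Connectors linking a head noun to its anatomical tail.
of
of the
in the
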