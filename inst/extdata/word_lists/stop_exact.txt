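# Candidates removed only when the whole surface equals a phrase here:
# bare anatomical words that are parts of phenotype terms but not
# phenotypes themselves ("hippocampus" vs "enlarged hippocampus").
hippocampus
neuroanatomy
brain
patient
patients
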