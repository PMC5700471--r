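# Nouns that frequently head phenotype terms ("abnormalities of the ear").
# One phrase per line; '#' starts a comment. Singular/plural both listed
# because surface forms are inflection-sensitive.
abnormality
abnormalities
malformation
malformations
anomaly
anomalies
defect
defects
deformity
deformities
pit
pits
aplasia
hypoplasia
dysplasia
tumour
tumours
tumor
tumors
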