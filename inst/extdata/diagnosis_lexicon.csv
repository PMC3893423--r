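term,category
diabetes,diabetes
sugar diabetes,diabetes
diabetes mellitus,diabetes
diabetes type 1,diabetes
diabetes type 2,diabetes
type 1 diabetes,diabetes
type 2 diabetes,diabetes
grade 2 diabetes,diabetes
controlled diabetes,diabetes
diet controlled diabetes,diabetes
self managed diabetes,diabetes
pre-diabetes,uncertain
pre diabetes,uncertain
prediabetes,uncertain
borderline diabetes,uncertain
diabetes insipidus,uncertain
impaired glucose tolerance,uncertain
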