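component,count
tickbox,23981
free_text,119
insulin,58
cohort,266848
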