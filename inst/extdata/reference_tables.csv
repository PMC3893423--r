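source,tp,fp,fn,tn,uncertain_pos,uncertain_neg
apdc,15143,3943,2904,169983,557,596
mbs,20340,3664,11514,228157,787,590
pbs,14465,5780,663,191068,770,394
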