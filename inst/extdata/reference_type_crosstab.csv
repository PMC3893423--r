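algorithm,hospital,count
type1,type1,314
type1,type2,383
type1,gestational_other,2
type1,unspecified,1
type1,no_diabetes_code,56
type2,type1,451
type2,type2,13822
type2,gestational_other,18
type2,unspecified,45
type2,no_diabetes_code,3664
gestational_other,type1,26
gestational_other,type2,61
gestational_other,gestational_other,20
gestational_other,unspecified,0
gestational_other,no_diabetes_code,223
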