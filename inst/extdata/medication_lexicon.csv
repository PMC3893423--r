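term,class
insulin,insulin
lantus,insulin
levemir,insulin
novorapid,insulin
novomix,insulin
humalog,insulin
humulin,insulin
protaphane,insulin
actrapid,insulin
mixtard,insulin
apidra,insulin
hypurin,insulin
glargine,insulin
detemir,insulin
aspart,insulin
lispro,insulin
glulisine,insulin
isophane,insulin
metformin,biguanide
diabex,biguanide
diaformin,biguanide
glucophage,biguanide
formet,biguanide
glucomet,biguanide
metex,biguanide
gliclazide,sulphonylurea
diamicron,sulphonylurea
nidem,sulphonylurea
glyade,sulphonylurea
glipizide,sulphonylurea
minidiab,sulphonylurea
melizide,sulphonylurea
glibenclamide,sulphonylurea
daonil,sulphonylurea
glimel,sulphonylurea
glimepiride,sulphonylurea
amaryl,sulphonylurea
dimirel,sulphonylurea
pioglitazone,thiazolidinedione
actos,thiazolidinedione
rosiglitazone,thiazolidinedione
avandia,thiazolidinedione
acarbose,alpha_glucosidase_inhibitor
glucobay,alpha_glucosidase_inhibitor
sitagliptin,dpp4_inhibitor
januvia,dpp4_inhibitor
vildagliptin,dpp4_inhibitor
galvus,dpp4_inhibitor
avandamet,premixed_oha
glucovance,premixed_oha
janumet,premixed_oha
exenatide,exenatide
byetta,exenatide
repaglinide,meglitinide
novonorm,meglitinide
nateglinide,meglitinide
starlix,meglitinide
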