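synonym,substance
sodium valproate,Valproic acid
valproate,Valproic acid
valproate sodium,Valproic acid
valproate semisodium,Valproic acid
valproic acid and sodium valproate,Valproic acid
phenobarbitone,Phenobarbital
methylphenobarbitone,Methylphenobarbital
clorazepate,Clorazepate potassium
dipotassium clorazepate,Clorazepate potassium
eslicarbazepine acetate,Eslicarbazepine
gamma-aminobutyric acid,Aminobutyric acid
fosphenytoin sodium,Fosphenytoin
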