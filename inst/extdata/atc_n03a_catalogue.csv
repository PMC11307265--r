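substance,atc_code,chemical_subgroup,era,weight
Phenobarbital,N03AA,barbiturates,old,4607
Barbexaclone,N03AA,barbiturates,old,24
Metharbital,N03AA,barbiturates,old,1
Methylphenobarbital,N03AA,barbiturates,old,172
Primidone,N03AA,barbiturates,old,765
Clobazam,N03AE,benzodiazepines,new,4245
Clonazepam,N03AE,benzodiazepines,old,14679
Clorazepate potassium,N03AE,benzodiazepines,old,7
Carbamazepine,N03AF,carboxamides,old,23294
Eslicarbazepine,N03AF,carboxamides,new,1980
Oxcarbazepine,N03AF,carboxamides,new,6678
Rufinamide,N03AF,carboxamides,new,343
Aminobutyric acid,N03AG,fatty_acid_derivatives,old,19
Tiagabine,N03AG,fatty_acid_derivatives,new,308
Valproic acid,N03AG,fatty_acid_derivatives,old,35235
Vigabatrin,N03AG,fatty_acid_derivatives,new,6171
Ethotoin,N03AB,hydantoins,old,4
Fosphenytoin,N03AB,hydantoins,new,713
Mephenytoin,N03AB,hydantoins,old,11
Phenytoin,N03AB,hydantoins,old,9739
Beclamide,N03AX,other_antiepileptics,old,2
Brivaracetam,N03AX,other_antiepileptics,new,2944
Cannabidiol,N03AX,other_antiepileptics,unclassified,4722
Cenobamate,N03AX,other_antiepileptics,new,389
Felbamate,N03AX,other_antiepileptics,new,189
Fenfluramine,N03AX,other_antiepileptics,new,309
Gabapentin,N03AX,other_antiepileptics,new,19369
Lacosamide,N03AX,other_antiepileptics,new,10542
Lamotrigine,N03AX,other_antiepileptics,new,22835
Levetiracetam,N03AX,other_antiepileptics,new,29146
Perampanel,N03AX,other_antiepileptics,new,2413
Phenacemide,N03AX,other_antiepileptics,old,2
Pheneturide,N03AX,other_antiepileptics,old,2
Pregabalin,N03AX,other_antiepileptics,new,57497
Retigabine,N03AX,other_antiepileptics,new,463
Stiripentol,N03AX,other_antiepileptics,new,614
Sultiame,N03AX,other_antiepileptics,old,170
Topiramate,N03AX,other_antiepileptics,new,13214
Zonisamide,N03AX,other_antiepileptics,new,2243
Paramethadione,N03AC,oxazolidines,old,1
Trimethadione,N03AC,oxazolidines,old,9
Ethosuximide,N03AD,succinimides,old,580
Mesuximide,N03AD,succinimides,old,43
Phensuximide,N03AD,succinimides,old,1
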