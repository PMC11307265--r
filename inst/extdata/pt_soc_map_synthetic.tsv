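pt	soc
Seizure	Nervous system disorders
Somnolence	Nervous system disorders
Dizziness	Nervous system disorders
Headache	Nervous system disorders
Tremor	Nervous system disorders
Memory impairment	Nervous system disorders
Sudden unexplained death in epilepsy	Nervous system disorders
Drug ineffective	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Drug interaction	General disorders and administration site conditions
Pain	General disorders and administration site conditions
Off label use	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Toxicity to various agents	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Aggression	Psychiatric disorders
Depression	Psychiatric disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Suicide attempt	Psychiatric disorders
Anaemia	Blood and lymphatic system disorders
Thrombocytopenia	Blood and lymphatic system disorders
Agranulocytosis	Blood and lymphatic system disorders
Foetal anticonvulsant syndrome	Congenital, familial and genetic disorders
Foetal valproate syndrome	Congenital, familial and genetic disorders
Spina bifida	Congenital, familial and genetic disorders
Hepatotoxicity	Hepatobiliary disorders
Hepatic failure	Hepatobiliary disorders
Jaundice	Hepatobiliary disorders
Bradycardia	Cardiac disorders
Tachycardia	Cardiac disorders
Cardiac arrest	Cardiac disorders
Weight increased	Investigations
Hepatic enzyme increased	Investigations
Blood sodium decreased	Investigations
Rash	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Stevens-Johnson syndrome	Skin and subcutaneous tissue disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Vertigo	Ear and labyrinth disorders
Tinnitus	Ear and labyrinth disorders
Hypothyroidism	Endocrine disorders
Diplopia	Eye disorders
Vision blurred	Eye disorders
Hypersensitivity	Immune system disorders
Pneumonia	Infections and infestations
Nasopharyngitis	Infections and infestations
Hyponatraemia	Metabolism and nutrition disorders
Decreased appetite	Metabolism and nutrition disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Osteoporosis	Musculoskeletal and connective tissue disorders
Hepatic neoplasm	Neoplasms benign, malignant and unspecified (incl. cysts and polyps)
Abortion spontaneous	Pregnancy, puerperium and perinatal conditions
Renal failure	Renal and urinary disorders
Erectile dysfunction	Reproductive system and breast disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Drug abuse	Social circumstances
Hypotension	Vascular disorders
Product quality issue	Product issues
Epilepsy surgery	Surgical and medical procedures
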