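genome_id	role
parasite_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
parasite_like	6-phosphofructokinase (EC 2.7.1.11)
parasite_like	6-phosphofructokinase, minor isozyme PfkB (EC 2.7.1.11)
parasite_like	Acetate kinase (EC 2.7.2.1)
parasite_like	Acetate permease ActP
parasite_like	Adenylate kinase (EC 2.7.4.3)
parasite_like	D-lactate dehydrogenase (EC 1.1.1.28)
parasite_like	Dihydrolipoamide acetyltransferase (EC 2.3.1.12)
parasite_like	Dihydrolipoamide dehydrogenase (EC 1.8.1.4)
parasite_like	Enolase (EC 4.2.1.11)
parasite_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
parasite_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
parasite_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
parasite_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
parasite_like	Lactate permease LctP
parasite_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
parasite_like	Phosphate acetyltransferase (EC 2.3.1.8)
parasite_like	Phosphoenolpyruvate-protein phosphotransferase PtsI (EC 2.7.3.9)
parasite_like	Phosphoglycerate kinase (EC 2.7.2.3)
parasite_like	Phosphoglycerate mutase (EC 5.4.2.11)
parasite_like	PTS system, glucose-specific IIBC component (EC 2.7.1.199)
parasite_like	Pyruvate dehydrogenase E1 component (EC 1.2.4.1)
parasite_like	Pyruvate kinase (EC 2.7.1.40)
parasite_like	Triosephosphate isomerase (EC 5.3.1.1)
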