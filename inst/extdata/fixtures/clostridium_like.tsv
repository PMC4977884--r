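genome_id	role
clostridium_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
clostridium_like	3-hydroxybutyryl-CoA dehydratase (EC 4.2.1.55)
clostridium_like	3-hydroxybutyryl-CoA dehydrogenase (EC 1.1.1.157)
clostridium_like	6-phosphofructokinase (EC 2.7.1.11)
clostridium_like	6-phosphofructokinase, minor isozyme PfkB (EC 2.7.1.11)
clostridium_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
clostridium_like	6-phosphogluconolactonase (EC 3.1.1.31)
clostridium_like	Acetaldehyde dehydrogenase, acetylating (EC 1.2.1.10)
clostridium_like	Acetate kinase (EC 2.7.2.1)
clostridium_like	Acetate permease ActP
clostridium_like	Acetoacetate decarboxylase (EC 4.1.1.4)
clostridium_like	Acetoacetyl-CoA:acetate CoA-transferase (EC 2.8.3.8)
clostridium_like	Acetyl-CoA acetyltransferase (EC 2.3.1.9)
clostridium_like	Adenylate kinase (EC 2.7.4.3)
clostridium_like	Alcohol dehydrogenase (EC 1.1.1.1)
clostridium_like	Butyraldehyde dehydrogenase (EC 1.2.1.57)
clostridium_like	Butyrate kinase (EC 2.7.2.7)
clostridium_like	Butyryl-CoA dehydrogenase (EC 1.3.8.1)
clostridium_like	D-lactate dehydrogenase (EC 1.1.1.28)
clostridium_like	Enolase (EC 4.2.1.11)
clostridium_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
clostridium_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
clostridium_like	Ferredoxin:NAD+ oxidoreductase (EC 1.18.1.3)
clostridium_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
clostridium_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
clostridium_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
clostridium_like	Iron-only hydrogenase (EC 1.12.7.2)
clostridium_like	Lactate permease LctP
clostridium_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
clostridium_like	NADH-dependent butanol dehydrogenase (EC 1.1.1.-)
clostridium_like	Phosphate acetyltransferase (EC 2.3.1.8)
clostridium_like	Phosphate butyryltransferase (EC 2.3.1.19)
clostridium_like	Phosphoenolpyruvate-protein phosphotransferase PtsI (EC 2.7.3.9)
clostridium_like	Phosphoglycerate kinase (EC 2.7.2.3)
clostridium_like	Phosphoglycerate mutase (EC 5.4.2.11)
clostridium_like	PTS system, glucose-specific IIBC component (EC 2.7.1.199)
clostridium_like	Pyruvate carboxylase (EC 6.4.1.1)
clostridium_like	Pyruvate kinase (EC 2.7.1.40)
clostridium_like	Pyruvate:ferredoxin oxidoreductase (EC 1.2.7.1)
clostridium_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
clostridium_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
clostridium_like	Short-chain fatty acid transporter AtoE
clostridium_like	Transaldolase (EC 2.2.1.2)
clostridium_like	Transketolase (EC 2.2.1.1)
clostridium_like	Triosephosphate isomerase (EC 5.3.1.1)
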