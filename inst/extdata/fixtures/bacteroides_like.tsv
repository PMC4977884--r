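genome_id	role
bacteroides_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
bacteroides_like	6-phosphofructokinase (EC 2.7.1.11)
bacteroides_like	6-phosphofructokinase, minor isozyme PfkB (EC 2.7.1.11)
bacteroides_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
bacteroides_like	6-phosphogluconolactonase (EC 3.1.1.31)
bacteroides_like	Acetate kinase (EC 2.7.2.1)
bacteroides_like	Acetate permease ActP
bacteroides_like	Adenylate kinase (EC 2.7.4.3)
bacteroides_like	Cytochrome bd ubiquinol oxidase subunit I (EC 1.10.3.14)
bacteroides_like	D-lactate dehydrogenase (EC 1.1.1.28)
bacteroides_like	Enolase (EC 4.2.1.11)
bacteroides_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
bacteroides_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
bacteroides_like	Formate transporter FocA
bacteroides_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
bacteroides_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
bacteroides_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
bacteroides_like	Lactate permease LctP
bacteroides_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
bacteroides_like	NADH dehydrogenase, type II (EC 1.6.99.3)
bacteroides_like	Phosphate acetyltransferase (EC 2.3.1.8)
bacteroides_like	Phosphoenolpyruvate carboxylase (EC 4.1.1.31)
bacteroides_like	Phosphoenolpyruvate-protein phosphotransferase PtsI (EC 2.7.3.9)
bacteroides_like	Phosphoglycerate kinase (EC 2.7.2.3)
bacteroides_like	Phosphoglycerate mutase (EC 5.4.2.11)
bacteroides_like	PTS system, glucose-specific IIBC component (EC 2.7.1.199)
bacteroides_like	Pyruvate formate-lyase (EC 2.3.1.54)
bacteroides_like	Pyruvate kinase (EC 2.7.1.40)
bacteroides_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
bacteroides_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
bacteroides_like	Transaldolase (EC 2.2.1.2)
bacteroides_like	Transketolase (EC 2.2.1.1)
bacteroides_like	Triosephosphate isomerase (EC 5.3.1.1)
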