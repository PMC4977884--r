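genome_id	role
pseudomonas_like	2-keto-3-deoxy-6-phosphogluconate aldolase (EC 4.1.2.14)
pseudomonas_like	2-oxoglutarate dehydrogenase E1 component (EC 1.2.4.2)
pseudomonas_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
pseudomonas_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
pseudomonas_like	6-phosphogluconolactonase (EC 3.1.1.31)
pseudomonas_like	Aconitate hydratase (EC 4.2.1.3)
pseudomonas_like	Adenylate kinase (EC 2.7.4.3)
pseudomonas_like	Citrate synthase (EC 2.3.3.16)
pseudomonas_like	Cytochrome bo terminal oxidase subunit I (EC 1.10.3.10)
pseudomonas_like	D-lactate dehydrogenase (EC 1.1.1.28)
pseudomonas_like	Dicarboxylate transporter DctA
pseudomonas_like	Dihydrolipoamide acetyltransferase (EC 2.3.1.12)
pseudomonas_like	Dihydrolipoamide dehydrogenase (EC 1.8.1.4)
pseudomonas_like	Dihydrolipoamide succinyltransferase (EC 2.3.1.61)
pseudomonas_like	Enolase (EC 4.2.1.11)
pseudomonas_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
pseudomonas_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
pseudomonas_like	Fructose-1,6-bisphosphatase (EC 3.1.3.11)
pseudomonas_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
pseudomonas_like	Fumarate hydratase (EC 4.2.1.2)
pseudomonas_like	Galactose/glucose:H+ symporter GalP
pseudomonas_like	Glucokinase (EC 2.7.1.2)
pseudomonas_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
pseudomonas_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
pseudomonas_like	Glycerol kinase (EC 2.7.1.30)
pseudomonas_like	Glycerol uptake facilitator protein GlpF
pseudomonas_like	Glycerol-3-phosphate dehydrogenase, aerobic (EC 1.1.5.3)
pseudomonas_like	Isocitrate dehydrogenase, NADP-dependent (EC 1.1.1.42)
pseudomonas_like	Isocitrate lyase (EC 4.1.3.1)
pseudomonas_like	Lactate permease LctP
pseudomonas_like	Malate dehydrogenase (EC 1.1.1.37)
pseudomonas_like	Malate synthase (EC 2.3.3.9)
pseudomonas_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
pseudomonas_like	NAD-dependent malic enzyme (EC 1.1.1.38)
pseudomonas_like	NAD(P) transhydrogenase subunit alpha (EC 7.1.1.1)
pseudomonas_like	NADH dehydrogenase, type II (EC 1.6.99.3)
pseudomonas_like	NADH-quinone oxidoreductase subunit NuoB (EC 1.6.5.11)
pseudomonas_like	NADH-quinone oxidoreductase subunit NuoL (EC 1.6.5.11)
pseudomonas_like	NADP-dependent malic enzyme (EC 1.1.1.40)
pseudomonas_like	Nitrate/nitrite antiporter NarK
pseudomonas_like	Phosphoenolpyruvate carboxykinase ATP (EC 4.1.1.49)
pseudomonas_like	Phosphoenolpyruvate carboxylase (EC 4.1.1.31)
pseudomonas_like	Phosphoenolpyruvate synthase (EC 2.7.9.2)
pseudomonas_like	Phosphogluconate dehydratase (EC 4.2.1.12)
pseudomonas_like	Phosphoglycerate kinase (EC 2.7.2.3)
pseudomonas_like	Phosphoglycerate mutase (EC 5.4.2.11)
pseudomonas_like	Pyruvate dehydrogenase E1 component (EC 1.2.4.1)
pseudomonas_like	Pyruvate kinase (EC 2.7.1.40)
pseudomonas_like	Respiratory nitrate reductase alpha chain (EC 1.7.5.1)
pseudomonas_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
pseudomonas_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
pseudomonas_like	Soluble pyridine nucleotide transhydrogenase (EC 1.6.1.1)
pseudomonas_like	Succinate dehydrogenase flavoprotein subunit (EC 1.3.5.1)
pseudomonas_like	Succinyl-CoA ligase ADP-forming alpha chain (EC 6.2.1.5)
pseudomonas_like	Succinyl-CoA ligase ADP-forming beta chain (EC 6.2.1.5)
pseudomonas_like	Transaldolase (EC 2.2.1.2)
pseudomonas_like	Transketolase (EC 2.2.1.1)
pseudomonas_like	Triosephosphate isomerase (EC 5.3.1.1)
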