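genome_id	role
acinetobacter_like	2-keto-3-deoxy-6-phosphogluconate aldolase (EC 4.1.2.14)
acinetobacter_like	2-oxoglutarate dehydrogenase E1 component (EC 1.2.4.2)
acinetobacter_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
acinetobacter_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
acinetobacter_like	Aconitate hydratase (EC 4.2.1.3)
acinetobacter_like	Adenylate kinase (EC 2.7.4.3)
acinetobacter_like	Citrate synthase (EC 2.3.3.16)
acinetobacter_like	Cytochrome bd ubiquinol oxidase subunit I (EC 1.10.3.14)
acinetobacter_like	Cytochrome bo terminal oxidase subunit I (EC 1.10.3.10)
acinetobacter_like	Dicarboxylate transporter DctA
acinetobacter_like	Dihydrolipoamide acetyltransferase (EC 2.3.1.12)
acinetobacter_like	Dihydrolipoamide dehydrogenase (EC 1.8.1.4)
acinetobacter_like	Dihydrolipoamide succinyltransferase (EC 2.3.1.61)
acinetobacter_like	Enolase (EC 4.2.1.11)
acinetobacter_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
acinetobacter_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
acinetobacter_like	Fructose-1,6-bisphosphatase (EC 3.1.3.11)
acinetobacter_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
acinetobacter_like	Fumarate hydratase (EC 4.2.1.2)
acinetobacter_like	Galactose/glucose:H+ symporter GalP
acinetobacter_like	Glucokinase (EC 2.7.1.2)
acinetobacter_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
acinetobacter_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
acinetobacter_like	Glycerol kinase (EC 2.7.1.30)
acinetobacter_like	Glycerol uptake facilitator protein GlpF
acinetobacter_like	Glycerol-3-phosphate dehydrogenase, aerobic (EC 1.1.5.3)
acinetobacter_like	Isocitrate dehydrogenase, NADP-dependent (EC 1.1.1.42)
acinetobacter_like	Isocitrate lyase (EC 4.1.3.1)
acinetobacter_like	Malate dehydrogenase (EC 1.1.1.37)
acinetobacter_like	Malate synthase (EC 2.3.3.9)
acinetobacter_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
acinetobacter_like	NAD-dependent malic enzyme (EC 1.1.1.38)
acinetobacter_like	NADH-quinone oxidoreductase subunit NuoB (EC 1.6.5.11)
acinetobacter_like	NADH-quinone oxidoreductase subunit NuoL (EC 1.6.5.11)
acinetobacter_like	Phosphoenolpyruvate carboxykinase ATP (EC 4.1.1.49)
acinetobacter_like	Phosphogluconate dehydratase (EC 4.2.1.12)
acinetobacter_like	Phosphoglycerate kinase (EC 2.7.2.3)
acinetobacter_like	Phosphoglycerate mutase (EC 5.4.2.11)
acinetobacter_like	Pyruvate dehydrogenase E1 component (EC 1.2.4.1)
acinetobacter_like	Pyruvate kinase (EC 2.7.1.40)
acinetobacter_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
acinetobacter_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
acinetobacter_like	Soluble pyridine nucleotide transhydrogenase (EC 1.6.1.1)
acinetobacter_like	Succinate dehydrogenase flavoprotein subunit (EC 1.3.5.1)
acinetobacter_like	Succinyl-CoA ligase ADP-forming alpha chain (EC 6.2.1.5)
acinetobacter_like	Succinyl-CoA ligase ADP-forming beta chain (EC 6.2.1.5)
acinetobacter_like	Transaldolase (EC 2.2.1.2)
acinetobacter_like	Transketolase (EC 2.2.1.1)
acinetobacter_like	Triosephosphate isomerase (EC 5.3.1.1)
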