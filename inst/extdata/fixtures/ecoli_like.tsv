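genome_id	role
ecoli_like	2-keto-3-deoxy-6-phosphogluconate aldolase (EC 4.1.2.14)
ecoli_like	2-oxoglutarate dehydrogenase E1 component (EC 1.2.4.2)
ecoli_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
ecoli_like	6-phosphofructokinase (EC 2.7.1.11)
ecoli_like	6-phosphofructokinase, minor isozyme PfkB (EC 2.7.1.11)
ecoli_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
ecoli_like	6-phosphogluconolactonase (EC 3.1.1.31)
ecoli_like	Acetaldehyde dehydrogenase, acetylating (EC 1.2.1.10)
ecoli_like	Acetate kinase (EC 2.7.2.1)
ecoli_like	Acetate permease ActP
ecoli_like	Acetyl-coenzyme A synthetase (EC 6.2.1.1)
ecoli_like	Aconitate hydratase (EC 4.2.1.3)
ecoli_like	Adenylate kinase (EC 2.7.4.3)
ecoli_like	Alcohol dehydrogenase (EC 1.1.1.1)
ecoli_like	Citrate synthase (EC 2.3.3.16)
ecoli_like	Cytochrome bd ubiquinol oxidase subunit I (EC 1.10.3.14)
ecoli_like	Cytochrome bo terminal oxidase subunit I (EC 1.10.3.10)
ecoli_like	D-lactate dehydrogenase (EC 1.1.1.28)
ecoli_like	Dicarboxylate transporter DctA
ecoli_like	Dihydrolipoamide acetyltransferase (EC 2.3.1.12)
ecoli_like	Dihydrolipoamide dehydrogenase (EC 1.8.1.4)
ecoli_like	Dihydrolipoamide succinyltransferase (EC 2.3.1.61)
ecoli_like	Enolase (EC 4.2.1.11)
ecoli_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
ecoli_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
ecoli_like	Formate transporter FocA
ecoli_like	Fructose-1,6-bisphosphatase (EC 3.1.3.11)
ecoli_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
ecoli_like	Fumarate hydratase (EC 4.2.1.2)
ecoli_like	Fumarate reductase flavoprotein subunit (EC 1.3.5.4)
ecoli_like	Galactose/glucose:H+ symporter GalP
ecoli_like	Glucokinase (EC 2.7.1.2)
ecoli_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
ecoli_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
ecoli_like	Glycerol kinase (EC 2.7.1.30)
ecoli_like	Glycerol uptake facilitator protein GlpF
ecoli_like	Glycerol-3-phosphate dehydrogenase, aerobic (EC 1.1.5.3)
ecoli_like	Glycerol-3-phosphate dehydrogenase, NAD-dependent (EC 1.1.1.8)
ecoli_like	Inorganic pyrophosphatase (EC 3.6.1.1)
ecoli_like	Isocitrate dehydrogenase, NADP-dependent (EC 1.1.1.42)
ecoli_like	Isocitrate lyase (EC 4.1.3.1)
ecoli_like	Lactate permease LctP
ecoli_like	Malate dehydrogenase (EC 1.1.1.37)
ecoli_like	Malate synthase (EC 2.3.3.9)
ecoli_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
ecoli_like	NAD-dependent malic enzyme (EC 1.1.1.38)
ecoli_like	NAD(P) transhydrogenase subunit alpha (EC 7.1.1.1)
ecoli_like	NADH dehydrogenase, type II (EC 1.6.99.3)
ecoli_like	NADH-quinone oxidoreductase subunit NuoB (EC 1.6.5.11)
ecoli_like	NADH-quinone oxidoreductase subunit NuoL (EC 1.6.5.11)
ecoli_like	NADP-dependent malic enzyme (EC 1.1.1.40)
ecoli_like	Nitrate/nitrite antiporter NarK
ecoli_like	Phosphate acetyltransferase (EC 2.3.1.8)
ecoli_like	Phosphoenolpyruvate carboxykinase ATP (EC 4.1.1.49)
ecoli_like	Phosphoenolpyruvate carboxylase (EC 4.1.1.31)
ecoli_like	Phosphoenolpyruvate synthase (EC 2.7.9.2)
ecoli_like	Phosphoenolpyruvate-protein phosphotransferase PtsI (EC 2.7.3.9)
ecoli_like	Phosphogluconate dehydratase (EC 4.2.1.12)
ecoli_like	Phosphoglycerate kinase (EC 2.7.2.3)
ecoli_like	Phosphoglycerate mutase (EC 5.4.2.11)
ecoli_like	PTS system, glucose-specific IIBC component (EC 2.7.1.199)
ecoli_like	Pyruvate dehydrogenase E1 component (EC 1.2.4.1)
ecoli_like	Pyruvate formate-lyase (EC 2.3.1.54)
ecoli_like	Pyruvate kinase (EC 2.7.1.40)
ecoli_like	Pyruvate oxidase (EC 1.2.5.1)
ecoli_like	Respiratory nitrate reductase alpha chain (EC 1.7.5.1)
ecoli_like	Ribokinase (EC 2.7.1.15)
ecoli_like	Ribose transport protein RbsC
ecoli_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
ecoli_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
ecoli_like	Soluble pyridine nucleotide transhydrogenase (EC 1.6.1.1)
ecoli_like	Succinate dehydrogenase flavoprotein subunit (EC 1.3.5.1)
ecoli_like	Succinyl-CoA ligase ADP-forming alpha chain (EC 6.2.1.5)
ecoli_like	Succinyl-CoA ligase ADP-forming beta chain (EC 6.2.1.5)
ecoli_like	Transaldolase (EC 2.2.1.2)
ecoli_like	Transketolase (EC 2.2.1.1)
ecoli_like	Trimethylamine-N-oxide reductase TorA (EC 1.7.2.3)
ecoli_like	Triosephosphate isomerase (EC 5.3.1.1)
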