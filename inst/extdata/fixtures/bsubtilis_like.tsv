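genome_id	role
bsubtilis_like	2-oxoglutarate dehydrogenase E1 component (EC 1.2.4.2)
bsubtilis_like	2,3-bisphosphoglycerate-independent phosphoglycerate mutase (EC 5.4.2.12)
bsubtilis_like	2,3-butanediol dehydrogenase (EC 1.1.1.4)
bsubtilis_like	6-phosphofructokinase (EC 2.7.1.11)
bsubtilis_like	6-phosphofructokinase, minor isozyme PfkB (EC 2.7.1.11)
bsubtilis_like	6-phosphogluconate dehydrogenase, decarboxylating (EC 1.1.1.44)
bsubtilis_like	6-phosphogluconolactonase (EC 3.1.1.31)
bsubtilis_like	Acetate kinase (EC 2.7.2.1)
bsubtilis_like	Acetate permease ActP
bsubtilis_like	Acetolactate synthase (EC 2.2.1.6)
bsubtilis_like	Aconitate hydratase (EC 4.2.1.3)
bsubtilis_like	Adenylate kinase (EC 2.7.4.3)
bsubtilis_like	Alpha-acetolactate decarboxylase (EC 4.1.1.5)
bsubtilis_like	Citrate synthase (EC 2.3.3.16)
bsubtilis_like	Cytochrome bo terminal oxidase subunit I (EC 1.10.3.10)
bsubtilis_like	D-lactate dehydrogenase (EC 1.1.1.28)
bsubtilis_like	Dihydrolipoamide acetyltransferase (EC 2.3.1.12)
bsubtilis_like	Dihydrolipoamide dehydrogenase (EC 1.8.1.4)
bsubtilis_like	Dihydrolipoamide succinyltransferase (EC 2.3.1.61)
bsubtilis_like	Enolase (EC 4.2.1.11)
bsubtilis_like	F0F1 ATP synthase subunit alpha (EC 7.1.2.2)
bsubtilis_like	F0F1 ATP synthase subunit beta (EC 7.1.2.2)
bsubtilis_like	Fructose-1,6-bisphosphatase (EC 3.1.3.11)
bsubtilis_like	Fructose-bisphosphate aldolase (EC 4.1.2.13)
bsubtilis_like	Fumarate hydratase (EC 4.2.1.2)
bsubtilis_like	Glucokinase (EC 2.7.1.2)
bsubtilis_like	Glucose-6-phosphate 1-dehydrogenase (EC 1.1.1.49)
bsubtilis_like	Glucose-6-phosphate isomerase (EC 5.3.1.9)
bsubtilis_like	Isocitrate dehydrogenase, NADP-dependent (EC 1.1.1.42)
bsubtilis_like	Lactate permease LctP
bsubtilis_like	Malate dehydrogenase (EC 1.1.1.37)
bsubtilis_like	NAD-dependent glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)
bsubtilis_like	NAD-dependent malic enzyme (EC 1.1.1.38)
bsubtilis_like	NADH dehydrogenase, type II (EC 1.6.99.3)
bsubtilis_like	Nitrate/nitrite antiporter NarK
bsubtilis_like	Phosphate acetyltransferase (EC 2.3.1.8)
bsubtilis_like	Phosphoenolpyruvate carboxykinase ATP (EC 4.1.1.49)
bsubtilis_like	Phosphoenolpyruvate-protein phosphotransferase PtsI (EC 2.7.3.9)
bsubtilis_like	Phosphoglycerate kinase (EC 2.7.2.3)
bsubtilis_like	Phosphoglycerate mutase (EC 5.4.2.11)
bsubtilis_like	PTS system, glucose-specific IIBC component (EC 2.7.1.199)
bsubtilis_like	Pyruvate dehydrogenase E1 component (EC 1.2.4.1)
bsubtilis_like	Pyruvate kinase (EC 2.7.1.40)
bsubtilis_like	Respiratory nitrate reductase alpha chain (EC 1.7.5.1)
bsubtilis_like	Ribose-5-phosphate isomerase (EC 5.3.1.6)
bsubtilis_like	Ribulose-phosphate 3-epimerase (EC 5.1.3.1)
bsubtilis_like	Soluble pyridine nucleotide transhydrogenase (EC 1.6.1.1)
bsubtilis_like	Succinate dehydrogenase flavoprotein subunit (EC 1.3.5.1)
bsubtilis_like	Succinyl-CoA ligase ADP-forming alpha chain (EC 6.2.1.5)
bsubtilis_like	Succinyl-CoA ligase ADP-forming beta chain (EC 6.2.1.5)
bsubtilis_like	Transaldolase (EC 2.2.1.2)
bsubtilis_like	Transketolase (EC 2.2.1.1)
bsubtilis_like	Triosephosphate isomerase (EC 5.3.1.1)
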