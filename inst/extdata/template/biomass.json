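{
  "id": "bio1",
  "name": "Core biomass (12 central-carbon precursors)",
  "comment": "Precursor stoichiometry (mmol per gDW) after Varma & Palsson's early E. coli core formulation; succinyl-CoA is the twelfth canonical precursor and its coefficient is a curation choice of this template. CoA-bound precursors return free CoA. Cofactor terms: ATP cost (growth-associated), NADPH consumed, NADH produced.",
  "precursors": [
    {"compound": "g6p_c",    "coefficient": 0.205},
    {"compound": "f6p_c",    "coefficient": 0.0709},
    {"compound": "r5p_c",    "coefficient": 0.8977},
    {"compound": "e4p_c",    "coefficient": 0.361},
    {"compound": "g3p_c",    "coefficient": 0.129},
    {"compound": "3pg_c",    "coefficient": 1.496},
    {"compound": "pep_c",    "coefficient": 0.5191},
    {"compound": "pyr_c",    "coefficient": 2.8328},
    {"compound": "accoa_c",  "coefficient": 3.7478},
    {"compound": "oaa_c",    "coefficient": 1.7867},
    {"compound": "akg_c",    "coefficient": 1.0789},
    {"compound": "succoa_c", "coefficient": 0.2}
  ],
  "coa_release": {"accoa_c": "coa_c", "succoa_c": "coa_c"},
  "cofactors": {"atp": 41.257, "nadph": 18.225, "nadh": -3.547}
}
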