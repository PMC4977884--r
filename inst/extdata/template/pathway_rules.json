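{
  "comment": "Boolean presence rules: a pathway is present iff every step lists at least one reaction found in the model. Steps marked with reactions that are spontaneous in the template are satisfied by construction; the transporter_exempt list names reactions that may be treated as spontaneous-diffusion exemptions when evaluating rules with exempt_transporters = TRUE.",
  "glucose_oxidation": ["glycolysis", "entner_doudoroff", "tca", "pentose_phosphate"],
  "fermentation": ["lactate", "acetate", "formate", "ethanol", "butanediol", "butyrate", "butanol", "acetone"],
  "transporter_exempt": ["ACt", "FORt", "BUTt", "D_LACt2"],
  "rules": {
    "glycolysis": [
      ["PGI"], ["PFK"], ["FBA"], ["TPI"], ["GAPD"], ["PGK"], ["PGM"], ["ENO"], ["PYK"]
    ],
    "entner_doudoroff": [
      ["G6PDH2r"], ["PGL"], ["EDD"], ["EDA"]
    ],
    "tca": [
      ["CS"], ["ACONT"], ["ICDHyr"], ["AKGDH"], ["SUCOAS"], ["SUCDi", "FRD7"], ["FUM"], ["MDH"]
    ],
    "pentose_phosphate": [
      ["G6PDH2r"], ["PGL"], ["GND"], ["RPE"], ["RPI"], ["TKT1"], ["TALA"], ["TKT2"]
    ],
    "lactate": [
      ["LDH_D"], ["D_LACt2"]
    ],
    "acetate": [
      ["PTAr"], ["ACKr"], ["ACt"]
    ],
    "formate": [
      ["PFL"], ["FORt"]
    ],
    "ethanol": [
      ["ACALD"], ["ALCD2x"], ["ETOHt"]
    ],
    "butanediol": [
      ["ACLS"], ["ACLDC"], ["BTDD"], ["BTDt"]
    ],
    "butyrate": [
      ["ACACT1r"], ["HACD1"], ["ECOAH1"], ["BTCOAR"], ["PBUTT"], ["BUTKr"], ["BUTt"]
    ],
    "butanol": [
      ["ACACT1r"], ["HACD1"], ["ECOAH1"], ["BTCOAR"], ["BTALDH"], ["BTOLDH"], ["BTOHt"]
    ],
    "acetone": [
      ["ACACT1r"], ["AACOAT"], ["ADCi"], ["ACEt"]
    ]
  }
}
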