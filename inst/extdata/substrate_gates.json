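{
  "Bo":   { "subfamilies": ["NIP", "XIP"], "groups": { "NIP": [5] } },
  "CO2":  { "subfamilies": ["PIP"] },
  "H2O2": { },
  "NH3":  { "subfamilies": ["TIP"] },
  "Si":   { "subfamilies": ["NIP"], "arR": "GSGR" },
  "U":    { "subfamilies": ["TIP", "XIP"] },
  "As":   { "subfamilies": ["NIP"] },
  "Sb":   { "subfamilies": ["NIP"] }
}
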