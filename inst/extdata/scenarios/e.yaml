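name: e
label: "combination: 10% of high risk wholly to dentists"
population_split:
  stratum: high
  fraction: 0.10
  cadre: dentist
rules:
  exam: dh_dth
  radiographs: dh_dth
  fluoride_varnish: eddn
  fissure_sealants: dh_dth
  oh_advice: eddn
  diet_advice: eddn
  vba: eddn
  restorative: dh_dth
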