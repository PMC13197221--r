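name: d
label: "intermediate skill mix: all three cadres"
rules:
  exam: dentist
  radiographs: dh_dth
  fluoride_varnish: eddn
  fissure_sealants: dh_dth
  oh_advice: dh_dth
  diet_advice: dh_dth
  vba: dh_dth
  restorative: dh_dth
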