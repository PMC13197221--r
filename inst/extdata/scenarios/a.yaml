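name: a
label: "no skill mix: dentists only"
rules:
  exam: dentist
  radiographs: dentist
  fluoride_varnish: dentist
  fissure_sealants: dentist
  oh_advice: dentist
  diet_advice: dentist
  vba: dentist
  restorative: dentist
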