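name: b
label: "no skill mix: DH/DThs only"
rules:
  exam: dh_dth
  radiographs: dh_dth
  fluoride_varnish: dh_dth
  fissure_sealants: dh_dth
  oh_advice: dh_dth
  diet_advice: dh_dth
  vba: dh_dth
  restorative: dh_dth
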