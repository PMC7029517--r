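# Canonical 11-node DMN parcellation: three Andrews-Hanna subsystems.
# Alternative parcellations use the same fields (abbreviation, name,
# subsystem) and load via read_subsystem_map().
- abbreviation: TP
  name: temporal pole
  subsystem: dorsomedial
- abbreviation: vlTC
  name: ventrolateral temporal cortex
  subsystem: dorsomedial
- abbreviation: dlTC
  name: dorsolateral temporal cortex
  subsystem: dorsomedial
- abbreviation: dmPFC
  name: dorsomedial prefrontal cortex
  subsystem: dorsomedial
- abbreviation: TPJ
  name: temporoparietal junction
  subsystem: dorsomedial
- abbreviation: pHG
  name: parahippocampal gyrus
  subsystem: medial_temporal
- abbreviation: HIP
  name: hippocampus
  subsystem: medial_temporal
- abbreviation: pIPL
  name: posterior inferior parietal lobule
  subsystem: medial_temporal
- abbreviation: PCU
  name: precuneus
  subsystem: midline_core
- abbreviation: PCC
  name: posterior cingulate cortex
  subsystem: midline_core
- abbreviation: vmPFC
  name: ventromedial prefrontal cortex
  subsystem: midline_core
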