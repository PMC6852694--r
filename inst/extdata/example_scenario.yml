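# Example scenario config: the standardized lake with a slower particle
# settling velocity and a higher dose, in calculated-KD mode.
base: euses_base
settling_velocity_m_d: 0.9
doc_mg_L: 4
partitioning:
  mode: isotherm
dose:
  mode: spike
  spike_conc_ug_L: 100
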