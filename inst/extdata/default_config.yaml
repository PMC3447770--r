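groups:
- name: mossy_fibers
  count: 24
  role: input
  subgroups: 1
- name: climbing_fibers
  count: 3
  role: input
  subgroups: 1
- name: granule
  count: 3300
  role: hidden
  subgroups: 1
- name: golgi
  count: 300
  role: hidden
  subgroups: 1
- name: basket
  count: 130
  role: hidden
  k: 65
  subgroups: 1
- name: purkinje
  count: 15
  role: hidden
  k: 15
  subgroups: 3
- name: deep_nuclei
  count: 2
  role: output
  k: 2
  subgroups: 1
connections:
- src: mossy_fibers
  dst: granule
  sign: excitatory
  strength: 4.0
  aligned: no
  plastic: yes
- src: granule
  dst: golgi
  sign: excitatory
  strength: 1.0
  aligned: no
  plastic: yes
- src: golgi
  dst: granule
  sign: inhibitory
  strength: 1.0
  aligned: no
  plastic: yes
- src: granule
  dst: basket
  sign: excitatory
  strength: 1.0
  aligned: no
  plastic: yes
- src: granule
  dst: purkinje
  sign: excitatory
  strength: 1.0
  aligned: no
  plastic: yes
- src: basket
  dst: purkinje
  sign: inhibitory
  strength: 1.0
  aligned: no
  plastic: yes
- src: climbing_fibers
  dst: purkinje
  sign: excitatory
  strength: 26000.0
  aligned: yes
  plastic: yes
- src: purkinje
  dst: deep_nuclei
  sign: inhibitory
  strength: 1.0
  aligned: no
  plastic: yes
- src: mossy_fibers
  dst: deep_nuclei
  sign: excitatory
  strength: 1.0
  aligned: no
  plastic: yes
- src: climbing_fibers
  dst: deep_nuclei
  sign: excitatory
  strength: 1.0
  aligned: no
  plastic: yes
dynamics:
  tau: 0.2
  cycles: 60
  gain: 1000.0
  threshold: 0.6
  aggregation: per_epoch
channels:
  E_excit: 1.0
  E_leak: 0.3
  E_inhib: 0.15
  gbar_excit: 1.0
  gbar_leak: 0.1
  gbar_inhib: 2.0
learning:
  epsilon: 0.8
  lambda: 0.0
  eps_cap: 4.0
  bias_max: 5.0
  cpca_correction: 1.0
training:
  n_samples: 140
  slow_change_bound: 0.15
  sample_dt: 0.25
  code: gray
  max_epochs: 2000
  criterion: 5.0e-07
  shuffle: no
include_nuclear_collaterals: yes
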