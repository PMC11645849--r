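generator: qalyval::write_fixture
n_patients: 50.0
seed: 2.0260101e+07
synthetic: yes
note: Fully synthetic data generated from the package's truth process; no real trial
  data.
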