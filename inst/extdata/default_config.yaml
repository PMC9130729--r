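rates:
  k1: 0.007
  k2: 0.017
  k3: 0.006
  k4: 0.018
  k5: 0.004
  k6: 0.013
p0: 1000.0
horizon: 30.0
replicates: 20
master_seed: 1
death:
  enabled: yes
  p_death: 0.55
  checkpoint_age: 15.0
schedule:
  lambda: 3.0
  rescue_factor: 10.0
  windows:
  - - 12.0
    - 30.0
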