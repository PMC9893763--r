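# Constant-rate oxygen consumption paired with CO2 production, superimposed
# on pure-oxygen gassing-in. Dissolved O2 settles at S*cb - R/kla, CO2 at its
# stripping balance near R/kla.
run:
  mode: react-uniform
species:
  - name: O2
  - name: CO2         # solubility defaults to 0.83
sparge:
  gas: {O2: 1.0}
  flow_slpm: 8
reaction:
  mode: uniform
  rates: {O2: -1.0e-5, CO2: 1.0e-5}   # mol/(L s)
numerics:
  duration: 600
  dt: 0.005
  seed: 2
  output_interval: 2
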