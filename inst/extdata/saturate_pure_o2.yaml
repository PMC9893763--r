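# Oxygen gassing-in of a non-reacting lab-scale stirred tank.
# Pure oxygen, 8 SLPM, 2 mm bubbles; dissolved O2 rises to S*cb.
run:
  mode: saturate
species:
  - name: O2          # solubility 0.032, M 32 g/mol, D 1e-9 m^2/s by default
sparge:
  gas: {O2: 1.0}
  flow_slpm: 8
  bubble_diameter: 0.002
  parcel_weight: 400
flow:
  kind: synthetic
numerics:
  duration: 600
  dt: 0.005
  seed: 1
  output_interval: 2
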