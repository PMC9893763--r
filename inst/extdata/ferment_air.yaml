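# Gluconic acid fermentation (Contois kinetics) under air sparging with a
# prescribed volumetric mass transfer coefficient. The Contois coefficients
# below are the package's ILLUSTRATIVE set; replace them with fitted values
# for any quantitative study.
run:
  mode: ferment
species:
  - name: O2
  - name: N2
sparge:
  gas: {O2: 0.21, N2: 0.79}
  flow_slpm: 8
reaction:
  mode: contois
  contois:
    mu_max: 0.15      # 1/h
    Ks_prime: 15      # g substrate / g biomass
    Ko_prime: 0.001   # g O2 / g biomass
    alpha: 2.5        # g P / g X
    beta: 0.9         # g P / (g X h)
    gamma: 2.2        # g S / g X
    lambda: 0.3       # g S / (g X h)
    delta: 0.4        # g O2 / g X
    phi: 0.08         # g O2 / (g X h)
  initial_state: {X: 1.5, P: 0, S: 150, O2: 0.0096}   # g/L
mass_transfer:
  prescribed_kla: 0.014   # 1/s
numerics:
  duration: 18000         # 5 h
  dt: 0.5
  seed: 3
  output_interval: 60
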