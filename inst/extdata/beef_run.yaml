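# Example run configuration: beef fixture farm, 2030 horizon.
farm: beef
horizon: "2030"
bundles: [baseline, LHF, TCN, Asp, CN1, CN2]
seed: 42
n_iter: 10000
policy:
  tax_rate: 80
  credit_price: 28
soil:
  top:
    clay_pct: 35
    initial_soc: 110
  deep:
    clay_pct: 35
    initial_soc: 55
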