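# Demonstration pipeline configuration on synthetic data.
data:
  source: synthetic
  synthetic:
    n_genes: 120
    responder_fraction: 0.15
    noise_sd: 0.25
    seed: 101
screen:
  alpha: 0.05
  fc_threshold: 1.5
  permutations: 500
  seed: 202
fit:
  restricted: true
  bmr_sd: 1.0
  bootstrap: 1000
  seed: 303
filters:
  ratio_max: 40
correction:
  enabled: false
  fu_plasma: 0.0033
  fu_invitro: 0.05506
pbtk:
  use_model: false
  anchor_conc: 181.0
  anchor_dose: 172.0
references:
  art_heds: [0.1, 3.5, 172.0]
  occupational_serum: [426.0, 1231.0, 19564.0]
  bfte: 0.75
output:
  dir: bmcber_demo_run
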