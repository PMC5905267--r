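# Example synthetic scene for the `afmtool synth` subcommand: two surface
# nanobubbles and one nanopit on a tilted, slightly noisy background.
shape: [128, 128]
seed: 7
background:
  tilt: [0.05, 0.12]
  noise_sd: 0.3
features:
  - kind: cap
    center: [40, 36]
    radius: 11
    height: 18
  - kind: cap
    center: [88, 64]
    radius: 8
    height: 12
  - kind: pit
    center: [52, 96]
    radius: 10
    depth: 15
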