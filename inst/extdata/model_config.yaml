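labels: [buk, puk, duk]
groups:
  unknown: 0.5
label_prior: uniform
k_prior: 0.5
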