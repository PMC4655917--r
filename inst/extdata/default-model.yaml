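# Default model and network configuration (all values equal the package
# defaults; copy and edit to override).
model:
  membrane_rate: 0.125        # 1/ms
  kir_slope: 5                # mV
  nmda_c1: 0.2
  nmda_c2: 0.062              # 1/mV
network:
  input:
    onset_mean: 64            # ms
    duration: 16              # ms (Gaussian SD)
    amplitude: 0.3
    targets: [left_HG, right_HG]
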