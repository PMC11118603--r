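# Example end-to-end experiment configuration for `iednet run` /
# run_experiment(). Values omitted here fall back to package defaults.
run_dir: iednet-run
synth:
  n_recordings: 3
  duration: 900          # seconds per recording
  sampling_rate: 250     # Hz; downsampled to 125 Hz in preprocessing
  event_rate: 31         # events/minute -> ~8% positive windows
  spike_fraction: 0.5
  background_amplitude: 6
  seed: 1
preprocess:
  k_early: [0]           # list of lookahead offsets to evaluate
  rule: onset
split:
  seed: 1
train:
  arch: gru              # gru | cnn
  select: ba             # ba | acc
  class_weights: "on"    # on | off
  epochs: 30             # full-study budget: 500
  lr: 1.0e-4
  batch_size: 512
  seed: 1
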