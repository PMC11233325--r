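# Demo pipeline configuration: simulate the bundled six-preset species set
# (juvenile stage) for one day and run the full analysis + stats battery.
seed: 20230101
mode: individual
stage: juvenile
species_presets: true
n_subjects: 3
fps: 15
n_days: 1
schedule:
  lights_on_h: 14
  lights_off_h: 10
  recording_start_zt: 1
min_duration_s: 60
window_h: 1
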