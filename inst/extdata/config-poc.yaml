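# Proof-of-concept acquisition: three mixed task blocks from 20 min,
# one combined task regressor.
frame_length_s: 60
scan_duration_min: 50
t_star_min: 25
filter_cutoff_min: 2.5
blood_volume_fraction: 0.05
seed: 1
combine_task: true
task:
  onsets_min: [20, 30, 40]
  duration_min: 5
  conditions: [mixed, mixed, mixed]
admin:
  bolus_fraction: 0.2
  infusion_duration_min: 50
  total_activity: 200
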