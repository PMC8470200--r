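# Example synthetic-subject profile: a lighter sleeper who naps more often
# than the default compliant subject.
subject_id: tms7
sleep_schedule:
  bedtime: "23:30"
  wake: "06:30"
  fall_asleep_mean: 18
hr_baseline:
  wake_mean: 82
  wake_sd: 5
  sleep_mean: 64
  sleep_sd: 2
nap_propensity:
  prob: 0.35
  duration_mean: 38
  duration_sd: 6
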