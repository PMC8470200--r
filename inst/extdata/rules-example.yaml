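# Example rulebase configuration: override selected default thresholds and
# set per-subject limits. Unlisted rules keep their defaults.
rules:
  Insomnia:
    threshold: 2400          # seconds to fall asleep in a day
  LackOfExercise:
    threshold: 6000          # steps per day
overrides:
  tms7:
    LackOfSleep:
      threshold: 360         # minutes: this subject needs more sleep
    Inactivity:
      window_min_duration: 240
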