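{
  "lr_01": {
    "quadrant": "low_registration",
    "min": 1,
    "max": 5
  },
  "lr_02": {
    "quadrant": "low_registration",
    "min": 1,
    "max": 5
  },
  "lr_03": {
    "quadrant": "low_registration",
    "min": 1,
    "max": 5
  },
  "lr_04": {
    "quadrant": "low_registration",
    "min": 1,
    "max": 5
  },
  "lr_05": {
    "quadrant": "low_registration",
    "min": 1,
    "max": 5
  },
  "sk_01": {
    "quadrant": "sensory_seeking",
    "min": 1,
    "max": 5
  },
  "sk_02": {
    "quadrant": "sensory_seeking",
    "min": 1,
    "max": 5
  },
  "sk_03": {
    "quadrant": "sensory_seeking",
    "min": 1,
    "max": 5
  },
  "sk_04": {
    "quadrant": "sensory_seeking",
    "min": 1,
    "max": 5
  },
  "sk_05": {
    "quadrant": "sensory_seeking",
    "min": 1,
    "max": 5
  },
  "ss_01": {
    "quadrant": "sensory_sensitivity",
    "min": 1,
    "max": 5
  },
  "ss_02": {
    "quadrant": "sensory_sensitivity",
    "min": 1,
    "max": 5
  },
  "ss_03": {
    "quadrant": "sensory_sensitivity",
    "min": 1,
    "max": 5
  },
  "ss_04": {
    "quadrant": "sensory_sensitivity",
    "min": 1,
    "max": 5
  },
  "ss_05": {
    "quadrant": "sensory_sensitivity",
    "min": 1,
    "max": 5
  },
  "av_01": {
    "quadrant": "sensory_avoiding",
    "min": 1,
    "max": 5
  },
  "av_02": {
    "quadrant": "sensory_avoiding",
    "min": 1,
    "max": 5
  },
  "av_03": {
    "quadrant": "sensory_avoiding",
    "min": 1,
    "max": 5
  },
  "av_04": {
    "quadrant": "sensory_avoiding",
    "min": 1,
    "max": 5
  },
  "av_05": {
    "quadrant": "sensory_avoiding",
    "min": 1,
    "max": 5
  }
}
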