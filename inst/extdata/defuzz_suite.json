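[
  {
    "modality": "brightness",
    "stimulus": 100,
    "duration_s": 25,
    "attention": "low",
    "stress": "high",
    "expected_category": "High Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 400,
    "duration_s": 40,
    "attention": "normal",
    "stress": "low",
    "expected_category": "Low Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 750,
    "duration_s": 10,
    "attention": "normal",
    "stress": "high",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 15,
    "duration_s": 10,
    "attention": "normal",
    "stress": "high",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 26,
    "duration_s": 25,
    "attention": "normal",
    "stress": "moderate",
    "expected_category": "Low Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 32,
    "duration_s": 40,
    "attention": "low",
    "stress": "high",
    "expected_category": "High Risk"
  },
  {
    "modality": "noise",
    "stimulus": 60,
    "duration_s": 25,
    "attention": "low",
    "stress": "low",
    "expected_category": "Low Risk"
  },
  {
    "modality": "noise",
    "stimulus": 70,
    "duration_s": 10,
    "attention": "normal",
    "stress": "high",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "noise",
    "stimulus": 80,
    "duration_s": 40,
    "attention": "low",
    "stress": "moderate",
    "expected_category": "High Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 32,
    "duration_s": 40,
    "attention": "normal",
    "stress": "low",
    "expected_category": "High Risk"
  },
  {
    "modality": "noise",
    "stimulus": 72,
    "duration_s": 40,
    "attention": "low",
    "stress": "high",
    "expected_category": "High Risk"
  },
  {
    "modality": "noise",
    "stimulus": 74,
    "duration_s": 35,
    "attention": "normal",
    "stress": "moderate",
    "expected_category": "High Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 100,
    "duration_s": 5,
    "attention": "normal",
    "stress": "low",
    "expected_category": "Low Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 100,
    "duration_s": 17,
    "attention": "normal",
    "stress": "high",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 15,
    "duration_s": 25,
    "attention": "low",
    "stress": "low",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 15,
    "duration_s": 40,
    "attention": "normal",
    "stress": "low",
    "expected_category": "High Risk"
  },
  {
    "modality": "noise",
    "stimulus": 60,
    "duration_s": 10,
    "attention": "normal",
    "stress": "low",
    "expected_category": "Low Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 400,
    "duration_s": 10,
    "attention": "low",
    "stress": "high",
    "expected_category": "Medium Risk"
  },
  {
    "modality": "temperature",
    "stimulus": 29.5,
    "duration_s": 40,
    "attention": "low",
    "stress": "high",
    "expected_category": "High Risk"
  },
  {
    "modality": "noise",
    "stimulus": 80,
    "duration_s": 10,
    "attention": "normal",
    "stress": "low",
    "expected_category": "Low Risk"
  },
  {
    "modality": "brightness",
    "stimulus": 750,
    "duration_s": 40,
    "attention": "low",
    "stress": "high",
    "expected_category": "High Risk"
  }
]
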