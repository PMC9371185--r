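[
  {
    "modality": "brightness",
    "stimulus_term": "Low",
    "category": "Low Risk",
    "strategy": "Brightness level is low. No immediate impact. Keep an eye on the child."
  },
  {
    "modality": "brightness",
    "stimulus_term": "Low",
    "category": "Medium Risk",
    "strategy": "Brightness level is low. Enhance indoor brightness (e.g., draw the curtains open). Keep observing."
  },
  {
    "modality": "brightness",
    "stimulus_term": "Low",
    "category": "High Risk",
    "strategy": "Brightness level is low. Enhance indoor brightness (e.g., draw the curtains open), use a phone to show pictures or videos that the child likes for comfort and attention."
  },
  {
    "modality": "brightness",
    "stimulus_term": "Moderate",
    "category": "Low Risk",
    "strategy": "Brightness level is moderate. No impact."
  },
  {
    "modality": "brightness",
    "stimulus_term": "Moderate",
    "category": "Medium Risk",
    "strategy": "Brightness level is moderate. Keep observing."
  },
  {
    "modality": "brightness",
    "stimulus_term": "Moderate",
    "category": "High Risk",
    "strategy": "Brightness level is moderate. Check other factors that may distract your child and provide comfort."
  },
  {
    "modality": "brightness",
    "stimulus_term": "High",
    "category": "Low Risk",
    "strategy": "Brightness level is high. No immediate impact. Keep an eye on the child."
  },
  {
    "modality": "brightness",
    "stimulus_term": "High",
    "category": "Medium Risk",
    "strategy": "Brightness level is high. Reduce indoor brightness (e.g., draw the curtains). Keep observing."
  },
  {
    "modality": "brightness",
    "stimulus_term": "High",
    "category": "High Risk",
    "strategy": "Brightness level is high. Reduce indoor brightness (e.g., draw the curtains), use a phone to show pictures or videos that the child likes for comfort and attention."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Low",
    "category": "Low Risk",
    "strategy": "Temperature level is low. No immediate impact. Keep an eye on the child."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Low",
    "category": "Medium Risk",
    "strategy": "Temperature level is low. Enhance temperature level (e.g., turn up the air-conditioner). Keep observing."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Low",
    "category": "High Risk",
    "strategy": "Temperature level is low. Enhance temperature level (e.g., turn up the air-conditioner). Provide some deep pressure (e.g., hugs or massage) input to child for comfort and attention."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Moderate",
    "category": "Low Risk",
    "strategy": "Temperature level is moderate. Keep observing."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Moderate",
    "category": "Medium Risk",
    "strategy": "Temperature level is moderate. Keep observing and check other factors."
  },
  {
    "modality": "temperature",
    "stimulus_term": "Moderate",
    "category": "High Risk",
    "strategy": "Temperature level is moderate. Check other factors that may distract your child and provide comfort."
  },
  {
    "modality": "temperature",
    "stimulus_term": "High",
    "category": "Low Risk",
    "strategy": "Temperature level is high. No immediate impact. Keep an eye on the child."
  },
  {
    "modality": "temperature",
    "stimulus_term": "High",
    "category": "Medium Risk",
    "strategy": "Temperature level is high. Reduce temperature level (e.g., turn on the fan). Keep observing."
  },
  {
    "modality": "temperature",
    "stimulus_term": "High",
    "category": "High Risk",
    "strategy": "Temperature level is high. Reduce temperature level (e.g., turn on the fan). Provide some deep pressure (e.g., hugs or massage) input to child for comfort and attention."
  },
  {
    "modality": "noise",
    "stimulus_term": "Low",
    "category": "Low Risk",
    "strategy": "Noise level is low. No impact."
  },
  {
    "modality": "noise",
    "stimulus_term": "Low",
    "category": "Medium Risk",
    "strategy": "Noise level is low. Keep observing."
  },
  {
    "modality": "noise",
    "stimulus_term": "Low",
    "category": "High Risk",
    "strategy": "Noise level is low. Check other factors that may distract your child; provide comfort and attention."
  },
  {
    "modality": "noise",
    "stimulus_term": "Moderate",
    "category": "Low Risk",
    "strategy": "Noise level is moderate. Check other factors that may distract your child."
  },
  {
    "modality": "noise",
    "stimulus_term": "Moderate",
    "category": "Medium Risk",
    "strategy": "Noise level is moderate-high. Keep observing."
  },
  {
    "modality": "noise",
    "stimulus_term": "Moderate",
    "category": "High Risk",
    "strategy": "Noise level is moderate-high. Try to reduce loud (e.g., play calming music) and comfort the child."
  },
  {
    "modality": "noise",
    "stimulus_term": "High",
    "category": "Low Risk",
    "strategy": "Noise level is high. No immediate impact. Keep an eye on the child."
  },
  {
    "modality": "noise",
    "stimulus_term": "High",
    "category": "Medium Risk",
    "strategy": "Noise level is high. Try to reduce loud (e.g., use noise-cancelling headphones). Keep observing."
  },
  {
    "modality": "noise",
    "stimulus_term": "High",
    "category": "High Risk",
    "strategy": "Noise level is high. Try to reduce loud (e.g., use noise-cancelling headphones or play calming music). Provide a fidget toy with texture that child likes for comfort and attention."
  }
]
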