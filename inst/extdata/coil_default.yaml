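name: representative-3T-body-gradient v1
R0_mm: 250.0
terms:
- axis: 'x'
  'n': 1
  m: 1
  type: cos
  coef: '1'
- axis: 'x'
  'n': 3
  m: 1
  type: cos
  coef: '-0.0396823745480779'
- axis: 'x'
  'n': 5
  m: 1
  type: cos
  coef: '0.00879636542956574'
- axis: 'y'
  'n': 1
  m: 1
  type: sin
  coef: '1'
- axis: 'y'
  'n': 3
  m: 1
  type: sin
  coef: '-0.0396823745480779'
- axis: 'y'
  'n': 5
  m: 1
  type: sin
  coef: '0.00879636542956574'
- axis: 'z'
  'n': 1
  m: 0
  type: cos
  coef: '1'
- axis: 'z'
  'n': 3
  m: 0
  type: cos
  coef: '-0.039403063497077'
- axis: 'z'
  'n': 5
  m: 0
  type: cos
  coef: '0.00887856050156774'
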