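A:
- - 0.95
  - 0.0125
  - 0.0125
  - 0.0125
  - 0.0125
- - 0.0125
  - 0.95
  - 0.0125
  - 0.0125
  - 0.0125
- - 0.0125
  - 0.0125
  - 0.95
  - 0.0125
  - 0.0125
- - 0.0125
  - 0.0125
  - 0.0125
  - 0.95
  - 0.0125
- - 0.0125
  - 0.0125
  - 0.0125
  - 0.0125
  - 0.95
B:
- - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.9
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.9
    - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.9
    - 0.0
    - 0.0
  - - 0.1
    - 0.1
    - 0.1
    - 1.0
    - 1.0
D:
- 1.0
- 0.0
- 0.0
- 0.0
- 0.0
labels:
  states:
  - A
  - B
  - C
  - D
  - silence
  outcomes:
  - A
  - B
  - C
  - D
  - silence
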