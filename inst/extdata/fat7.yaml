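peaks:
- ppm: -3.8
  amplitude: 0.087
- ppm: -3.4
  amplitude: 0.693
- ppm: -3.1
  amplitude: 0.128
- ppm: -2.68
  amplitude: 0.004
- ppm: -2.46
  amplitude: 0.039
- ppm: -1.95
  amplitude: 0.01
- ppm: -0.5
  amplitude: 0.039
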