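{
  "X3": 1,
  "X5": 1,
  "X7": 2,
  "X8": 1,
  "X9": 1,
  "X10": 2,
  "X11": 2
}
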