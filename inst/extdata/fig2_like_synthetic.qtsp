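{
  "format": "qtsp",
  "version": 1,
  "name": "fig2_like_synthetic",
  "n": 6,
  "origin": 1,
  "quotas": [0, 4, 3, 2, 2, 1],
  "Q": 7,
  "distances": [
    [0, 1, 3, 6, 8, 6],
    [1, 0, 9, 6, 2, 6],
    [3, 9, 0, 6, 2, 6],
    [6, 6, 6, 0, 6, 6],
    [8, 2, 2, 6, 0, 6],
    [6, 6, 6, 6, 6, 0]
  ]
}
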