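# Whisker pad grid layout.
# Rows A-E are grid rows 1-5; arcs 1-4 are grid columns 1-4.
# Straddlers (alpha, beta, gamma, delta) occupy column 0 beside rows A-D.
# Supra-orbital whiskers (lSO, sSO) sit dorsally at grid row -1.
# Each entry: whisker_id: [row, col]
whiskers:
  lSO: [-1, 0]
  sSO: [-1, 1]
  alpha: [1, 0]
  beta: [2, 0]
  gamma: [3, 0]
  delta: [4, 0]
  A1: [1, 1]
  A2: [1, 2]
  A3: [1, 3]
  A4: [1, 4]
  B1: [2, 1]
  B2: [2, 2]
  B3: [2, 3]
  B4: [2, 4]
  C1: [3, 1]
  C2: [3, 2]
  C3: [3, 3]
  C4: [3, 4]
  D1: [4, 1]
  D2: [4, 2]
  D3: [4, 3]
  D4: [4, 4]
  E1: [5, 1]
  E2: [5, 2]
  E3: [5, 3]
  E4: [5, 4]
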