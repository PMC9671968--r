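{
  "comment": "Synthetic stand-in emission parameter tables for the benchmark presets. Values are chosen once to emulate AU565-like phenotypes under low-dose lapatinib (durations in hours): 1-5 generations inside a 96 h observation window, later states cycling slower and dying more often. They are package data, not estimates from any experimental dataset.",
  "two_state_lifetime": {
    "schema": "lifetime",
    "states": [
      { "bern": [0.99], "shape": [30], "scale": [0.5] },
      { "bern": [0.88], "shape": [30], "scale": [1.1] }
    ]
  },
  "two_state_phase": {
    "schema": "phase_specific",
    "states": [
      { "bern": [0.99, 0.95], "shape": [20, 25], "scale": [0.25, 0.32] },
      { "bern": [0.88, 0.75], "shape": [20, 25], "scale": [0.60, 0.56] }
    ]
  },
  "five_state_phase": {
    "schema": "phase_specific",
    "states": [
      { "bern": [0.99, 0.95], "shape": [20, 25], "scale": [0.25, 0.32] },
      { "bern": [0.94, 0.90], "shape": [20, 25], "scale": [0.50, 0.48] },
      { "bern": [0.88, 0.82], "shape": [20, 25], "scale": [0.85, 0.68] },
      { "bern": [0.82, 0.75], "shape": [20, 25], "scale": [1.30, 0.92] },
      { "bern": [0.72, 0.62], "shape": [20, 25], "scale": [2.60, 1.70] }
    ]
  }
}
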