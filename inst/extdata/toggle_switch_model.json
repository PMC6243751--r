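{
  "nodes": [
    {
      "name": "X",
      "category": "transcription_factor"
    },
    {
      "name": "Y",
      "category": "transcription_factor"
    }
  ],
  "edges": [
    {
      "from": "X",
      "to": "X",
      "sign": 1,
      "weight": 1,
      "kinetics": "slow"
    },
    {
      "from": "X",
      "to": "Y",
      "sign": -1,
      "weight": 1,
      "kinetics": "slow"
    },
    {
      "from": "Y",
      "to": "X",
      "sign": -1,
      "weight": 1,
      "kinetics": "slow"
    },
    {
      "from": "Y",
      "to": "Y",
      "sign": 1,
      "weight": 1,
      "kinetics": "slow"
    }
  ],
  "activation": "step",
  "steepness": 10,
  "convergence_tol": 1e-06,
  "fast_relaxation_max_iters": 1000,
  "markers": ["X", "Y"],
  "clamps": []
}
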