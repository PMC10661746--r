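{
  "alpha": 0.05,
  "designs": [
    {"id": "CBZ + ISOP (25)", "varied": "CBZ",
     "adjuncts": [{"drug": "ISOP", "dose": 25}]},
    {"id": "CBZ + ISOP (50)", "varied": "CBZ",
     "adjuncts": [{"drug": "ISOP", "dose": 50}]},
    {"id": "PHT + ISOP (25)", "varied": "PHT",
     "adjuncts": [{"drug": "ISOP", "dose": 25}]},
    {"id": "PHT + ISOP (50)", "varied": "PHT",
     "adjuncts": [{"drug": "ISOP", "dose": 50}]},
    {"id": "PB + ISOP (25)", "varied": "PB",
     "adjuncts": [{"drug": "ISOP", "dose": 25}]},
    {"id": "PB + ISOP (50)", "varied": "PB",
     "adjuncts": [{"drug": "ISOP", "dose": 50}]},
    {"id": "VPA + ISOP (25)", "varied": "VPA",
     "adjuncts": [{"drug": "ISOP", "dose": 25}]},
    {"id": "VPA + ISOP (50)", "varied": "VPA",
     "adjuncts": [{"drug": "ISOP", "dose": 50}]},
    {"id": "CBZ + ISOP (25) + BOR (25)", "varied": "CBZ",
     "adjuncts": [{"drug": "ISOP", "dose": 25}, {"drug": "BOR", "dose": 25}],
     "pool_adjuncts_on": "ISOP"},
    {"id": "PHT + ISOP (25) + BOR (25)", "varied": "PHT",
     "adjuncts": [{"drug": "ISOP", "dose": 25}, {"drug": "BOR", "dose": 25}],
     "pool_adjuncts_on": "ISOP"},
    {"id": "PB + ISOP (25) + BOR (25)", "varied": "PB",
     "adjuncts": [{"drug": "ISOP", "dose": 25}, {"drug": "BOR", "dose": 25}],
     "pool_adjuncts_on": "ISOP"},
    {"id": "VPA + ISOP (25) + BOR (25)", "varied": "VPA",
     "adjuncts": [{"drug": "ISOP", "dose": 25}, {"drug": "BOR", "dose": 25}],
     "pool_adjuncts_on": "ISOP"}
  ]
}
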