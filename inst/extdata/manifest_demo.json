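{
  "name": "synthetic_demo",
  "seed": 42,
  "experiments": [
    {
      "name": "ramp_excitability",
      "type": "intrinsic",
      "cells": [
        {"id": "d1", "group": "dorsal",
         "simulate": {"params": {"E_L": -76, "R": 180, "C": 90, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 101}},
        {"id": "d2", "group": "dorsal",
         "simulate": {"params": {"E_L": -75.5, "R": 190, "C": 85, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 102}},
        {"id": "d3", "group": "dorsal",
         "simulate": {"params": {"E_L": -76.5, "R": 175, "C": 95, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 103}},
        {"id": "v1", "group": "ventral",
         "simulate": {"params": {"E_L": -73, "R": 240, "C": 75, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 104}},
        {"id": "v2", "group": "ventral",
         "simulate": {"params": {"E_L": -72.5, "R": 250, "C": 70, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 105}},
        {"id": "v3", "group": "ventral",
         "simulate": {"params": {"E_L": -73.5, "R": 230, "C": 80, "V_T": -58},
                      "protocol": {"kind": "ramp",
                                   "params": {"i_start": 0, "i_end": 100, "duration": 2}},
                      "seed": 106}}
      ]
    },
    {
      "name": "paired_pulse_50ms",
      "type": "paired_pulse",
      "slices": [
        {"id": "sl1", "group": "dorsal",
         "stp": {"U": 0.35, "tau_f": 120, "tau_d": 600}, "isi_ms": 50, "seed": 201},
        {"id": "sl2", "group": "dorsal",
         "stp": {"U": 0.32, "tau_f": 140, "tau_d": 550}, "isi_ms": 50, "seed": 202},
        {"id": "sl3", "group": "ventral",
         "stp": {"U": 0.2, "tau_f": 220, "tau_d": 480}, "isi_ms": 50, "seed": 203},
        {"id": "sl4", "group": "ventral",
         "stp": {"U": 0.22, "tau_f": 200, "tau_d": 500}, "isi_ms": 50, "seed": 204}
      ]
    },
    {
      "name": "transgene_expression",
      "type": "ddcq",
      "reference_group": "DH",
      "simulate": {"folds": {"DH": 5.88, "VH": 5.04},
                   "noise_sd": 0.15, "duplicates": 2,
                   "n_per_group": 7, "seed": 301}
    }
  ]
}
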