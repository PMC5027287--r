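{
  "comment": [
    "Default DNA target presets for the two-step Cas9-RNA binding scheme.",
    "Values are literature-derived single-molecule FRET measurements of",
    "SpCas9 target binding at 0.1 s time resolution: bimolecular",
    "association ~6e6 /M/s (reduced without PAM), sampling-mode lifetime",
    "~0.1 s for all targets, amplitude-weighted bound lifetimes ~0.5 s",
    "(5-20_mm), ~8 s (8-20_mm), ~16 s (9-20_mm), photobleach-limited",
    "(>3 min) for targets with 9 or more PAM-proximal matches, and FRET",
    "state means 0 / 0.42 / 0.92.",
    "Derived quantities: S-exit rate = 1/sampling_lifetime_s, split",
    "p_extend into S->H and (1-p_extend) into S->U. k_HU_s is chosen so",
    "the mean bound dwell sampling_lifetime_s + p_extend/k_HU_s equals",
    "the measured amplitude-weighted bound lifetime. Roadblock targets",
    "(9-12_mm, 5-8_mm) share the kinetics of their x-20_mm counterparts."
  ],
  "presets": [
    {"name": "cognate",  "mm_from": null, "mm_to": null,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 5.555556e-4, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "17-20_mm", "mm_from": 17, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 5.555556e-4, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "10-20_mm", "mm_from": 10, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 5.555556e-4, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "9-20_mm",  "mm_from": 9, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 0.050314465, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "9-12_mm",  "mm_from": 9, "mm_to": 12,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 0.050314465, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "8-20_mm",  "mm_from": 8, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 0.101265823, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "5-20_mm",  "mm_from": 5, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 2.0, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "5-8_mm",   "mm_from": 5, "mm_to": 8,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.8,
     "k_HU_s": 2.0, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "1-2_mm",   "mm_from": 1, "mm_to": 2,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0.001,
     "k_HU_s": 5.555556e-4, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "1-4_mm",   "mm_from": 1, "mm_to": 4,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0,
     "k_HU_s": 0, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "1-20_mm",  "mm_from": 1, "mm_to": 20,
     "kon_M_s": 6e6, "sampling_lifetime_s": 0.1, "p_extend": 0,
     "k_HU_s": 0, "fret_mid": 0.42, "fret_high": 0.92},
    {"name": "no_PAM",   "mm_from": null, "mm_to": null,
     "kon_M_s": 3e6, "sampling_lifetime_s": 0.1, "p_extend": 0,
     "k_HU_s": 0, "fret_mid": 0.42, "fret_high": 0.92}
  ]
}
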