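{
  "columns": ["Y", "X", "M1", "M2", "M3", "XM1", "XM2", "XM3"],
  "means": [40.832, 0, 0, 0, 0, 27.490, 21.365, 13.113],
  "sds": [13.487, 13.111, 6.315, 3.746, 3.014, 97.162, 56.157, 41.136],
  "corr_lower": [
    1,
    -0.343, 1,
    -0.308, 0.332, 1,
    -0.430, 0.435, 0.262, 1,
    -0.435, 0.332, 0.371, 0.381, 1,
    -0.089, 0.112, 0.018, 0.080, 0.032, 1,
    0.028, 0.107, 0.082, -0.069, -0.071, 0.372, 1,
    0.085, -0.032, 0.036, -0.078, -0.070, 0.488, 0.428, 1
  ],
  "n": 2133,
  "raw_means": {"X": 90.364, "M1": 24.635, "M2": 17.235, "M3": 16.038}
}
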