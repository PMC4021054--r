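{
  "file": "cadaver_bvtv.csv",
  "md5": "7195e2be4f6ccaeb8c1dd2083e6f06c0",
  "description": "Paired microCT and MR apparent BV/TV (%) for ten cadaveric knees (five donors), medial tibia; demographics retained for completeness but unused by the statistics.",
  "expected": {
    "spearman_rho_2dp": 0.83,
    "ci_low_2dp": 0.42,
    "ci_high_2dp": 0.96,
    "side_rhos_2dp": [0.80, 0.90]
  }
}
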