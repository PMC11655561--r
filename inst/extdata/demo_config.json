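{
  "out_dir": "engramap_demo",
  "seed": 1,
  "rows": 7,
  "cols": 9,
  "q_threshold": 0.1,
  "freezing_threshold": 37,
  "alpha": 0.05,
  "reference_group": "vehicle",
  "sim": {
    "roi": {
      "x_um": [60, 250, 520, 760, 880, 900, 820, 640, 400, 180, 40, 0],
      "y_um": [40, 0, 20, 90, 220, 380, 540, 660, 700, 640, 480, 240]
    },
    "hotspots": [
      {"center": [320, 480], "radius": 55, "amplitude": 40},
      {"center": [620, 300], "radius": 60, "amplitude": 35},
      {"center": [450, 200], "radius": 45, "amplitude": 25}
    ],
    "groups": [
      {"label": "vehicle", "baseline_count": 250, "hotspot_multiplier": 1,
       "freezing": {"means": {"training-post": 45, "reactivation": 65, "test": 60},
                    "sds": {"training-post": 12, "reactivation": 12, "test": 12}}},
      {"label": "mirdametinib_25", "baseline_count": 250, "hotspot_multiplier": 0.25,
       "freezing": {"means": {"training-post": 45, "reactivation": 65, "test": 30},
                    "sds": {"training-post": 12, "reactivation": 12, "test": 12}}},
      {"label": "sl327_50", "baseline_count": 250, "hotspot_multiplier": 0.25,
       "freezing": {"means": {"training-post": 45, "reactivation": 65, "test": 30},
                    "sds": {"training-post": 12, "reactivation": 12, "test": 12}}}
    ],
    "n_per_group": 6
  }
}
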