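{
  "name": "7plex",
  "droplet_volume_nl": 0.85,
  "min_droplets": 8000,
  "thresholds": { "FAM": 9300, "HEX": 1700 },
  "targets": [
    { "name": "A2704-12", "channel": "FAM", "role": "gm" },
    { "name": "MON89788", "channel": "FAM", "role": "gm" },
    { "name": "MON40-3-2", "channel": "FAM", "role": "gm" },
    { "name": "356043", "channel": "FAM", "role": "gm" },
    { "name": "A5547-127", "channel": "FAM", "role": "gm" },
    { "name": "MON87705", "channel": "FAM", "role": "gm" },
    { "name": "Le1", "channel": "HEX", "role": "endogene" }
  ]
}
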