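{
  "name": "11plex",
  "droplet_volume_nl": 0.85,
  "min_droplets": 8000,
  "thresholds": { "FAM": 18500, "HEX": 2000 },
  "targets": [
    { "name": "A2704-12", "channel": "FAM", "role": "gm" },
    { "name": "MON89788", "channel": "FAM", "role": "gm" },
    { "name": "MON40-3-2", "channel": "FAM", "role": "gm" },
    { "name": "356043", "channel": "FAM", "role": "gm" },
    { "name": "A5547-127", "channel": "FAM", "role": "gm" },
    { "name": "MON87705", "channel": "FAM", "role": "gm" },
    { "name": "DAS-68416-4", "channel": "FAM", "role": "gm" },
    { "name": "FG72", "channel": "FAM", "role": "gm" },
    { "name": "DAS-44406-6", "channel": "FAM", "role": "gm" },
    { "name": "DAS-81419-2", "channel": "FAM", "role": "gm" },
    { "name": "Le1", "channel": "HEX", "role": "endogene" }
  ]
}
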