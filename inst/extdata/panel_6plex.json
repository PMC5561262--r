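{
  "name": "6plex",
  "droplet_volume_nl": 0.85,
  "min_droplets": 8000,
  "thresholds": { "FAM": 13200, "HEX": 1600 },
  "targets": [
    { "name": "MON87701", "channel": "FAM", "role": "gm" },
    { "name": "MON87708", "channel": "FAM", "role": "gm" },
    { "name": "MON87769", "channel": "FAM", "role": "gm" },
    { "name": "305423", "channel": "FAM", "role": "gm" },
    { "name": "BPS-CV127-9", "channel": "FAM", "role": "gm" },
    { "name": "Le1", "channel": "HEX", "role": "endogene" }
  ]
}
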