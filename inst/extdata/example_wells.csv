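well_id,panel_id,n_droplets,droplet_volume_nl,reaction_volume_ul,clog,positives_FAM,positives_HEX
A01,6plex,16185,0.85,20,FALSE,133,9203
A02,6plex,15507,0.85,20,FALSE,139,8848
A03,6plex,16509,0.85,20,FALSE,163,9420
A04,6plex,16211,0.85,20,FALSE,122,9298
A05,6plex,12236,0.85,20,FALSE,95,7032
A06,6plex,16078,0.85,20,FALSE,136,9166
A07,6plex,12881,0.85,20,TRUE,130,7273
A08,6plex,7500,0.85,20,FALSE,129,7500
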