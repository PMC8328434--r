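taxon,volume_um3,law_a,law_b,law_m,detection_limit_per_ml,imax_cells_cry,imax_cells_nav
Cry,664,0.216,0.939,1,3.3,NA,NA
Nav,100,0.288,0.811,1,NA,NA,NA
Eup,26890,0.14,1,1,0.5,116,NA
Col1,9850,0.14,1,1,0.5,17.6,38.8
Col2,9850,0.14,1,1,0.5,18.6,12.1
Col3,9850,0.14,1,1,0.5,17.0,35.1
Bacteria,0.05,0.435,0.86,0.5,NA,NA,NA
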