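group,n,preop_lfpta_db_hl,postop_lfpta_db_hl,lfpta_shift_db_hl,diameter_mm,diameter_sd_mm,apical_angle_deg,apical_angle_sd_deg
perimodiolar,34,59.4,92.9,33.6,9.2,0.4,396.5,40.2
lateral_wall,14,48.1,99.1,51.0,9.4,0.6,294.1,41.9
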