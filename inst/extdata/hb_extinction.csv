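wavelength_nm,eps_hb,eps_hbo2
650,3750.12,368.00
700,1794.28,290.00
730,1102.20,390.00
750,1405.24,518.44
757,1594.00,577.00
760,1674.64,586.00
780,1075.44,710.00
800,761.72,816.04
805,718.00,830.00
850,691.32,1058.00
900,728.00,1198.00
950,690.00,1204.00
1000,651.00,1190.00
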