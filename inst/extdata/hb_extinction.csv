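wavelength_nm,eps_hbo,eps_hbr
730,390,1102
756,464,1548
796,766,782
866,1100,691
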