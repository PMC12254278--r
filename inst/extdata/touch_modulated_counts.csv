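region,modality,n_total,n_modulated,n_wide,n_narrow,n_both
BC,ephys,413,261,142,28,91
VPM,ephys,420,196,90,53,53
POm,ephys,261,129,70,23,36
ZIv,ephys,147,67,23,9,35
POm,calcium,162,78,34,31,13
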