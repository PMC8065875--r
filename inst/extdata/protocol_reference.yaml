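# Reference MR protocol of the simulated dynamic 3D T1-weighted spoiled
# gradient echo acquisition (1.5 T small-vessel-disease study protocol).
# Acquired resolution 0.9375 x 1.25 x 4 mm over a 24 x 24 x 18.4 cm FOV.
tr_s: 0.00824
te_s: 0.0031
flip_deg: 12
fov_mm: [240.0, 240.0, 184.0]
acquired_matrix: [256, 192, 46]
temporal_resolution_s: 73
n_pre: 1
n_post: 20
# gadoterate relaxivities at 1.5 T (package assumption, configurable)
r1_per_mM_s: 3.9
r2star_per_mM_s: 4.5
# target pre-contrast NAWM spatial signal-to-noise ratio
snr_nawm: 91.5
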