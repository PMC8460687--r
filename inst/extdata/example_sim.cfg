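# Example synthetic fixture: a 100 nm line pair with strong
# density-induced sharpening bias in the test channel.
structure = line_pair
separation_nm = 100
length_nm = 1000
field_size_nm = 2000
labelling_density_per_um = 100
appearances_mean = 5
precision_ref_nm = 25
precision_test_nm = 15
bias_fraction = 0.8
recon_pixel_nm = 10
seed = 1
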