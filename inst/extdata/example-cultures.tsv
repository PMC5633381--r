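culture_id	genotype	cells_plated_total_medium	dilution_total	colonies_total_medium	colonies_5foa	dilution_5foa
c1	cohesin_hypomorph	100	1e-04	100	50	0.01
c2	cohesin_hypomorph	100	1e-04	100	33	0.01
c3	cohesin_hypomorph	100	1e-04	100	25	0.01
c4	cohesin_hypomorph	100	1e-04	100	30	0.01
c5	cohesin_hypomorph	100	1e-04	100	41	0.01
c6	cohesin_hypomorph	100	1e-04	100	21	0.01
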