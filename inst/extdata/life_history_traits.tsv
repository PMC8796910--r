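trait	female	male	pooled
first_reproduction_age_months	12	●	●
neonate_mass_g	9.28	9.28	9.28
adult_mass_g	149.17	152.49	149.27
weaning_mass_g	19.75	20.66	19.75
independence_mass_g	53.09	49.3	49.98
adult_life_span_months	16.20	15.50	●
litter_size_mean	4.57	●	●
litters_per_year	2	●	●
adults_captured	532	405	937
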