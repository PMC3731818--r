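# Preset manipulation scenarios for the mouse HoxD cluster: the genetic
# engineering experiments the force model explains, plus its two testable
# predictions (del(i) alone, and the anchor-sparing inversion). region uses
# gene numbers; "i" is the intergenic region between Hoxd4 and Hoxd8.
# expected_downregulated marks the quantitative-collinearity side effect.
scenario_id	kind	region	probe	profile_ref	expected_verdict	expected_downregulated
del_8_10	deletion	8-10	11	uniform	UNCHANGED	FALSE
del_i_8_10	deletion	i-8-10	11	stiff_del_i_8_10	ANTERIORIZED_WITH_GAIN	FALSE
del_10_12	deletion	10-12	13	uniform	UNCHANGED	FALSE
del_9_12	deletion	9-12	13	soft_del_9_12	SILENCED	FALSE
del_posterior_12_13	deletion	12-13	11	uniform	POSTERIORIZED_DELAYED	FALSE
dup_posterior_12_13	duplication	12-13	11	uniform	ANTERIORIZED	TRUE
split_fixed_end	split_inversion	fixed_end	11	uniform	ANTERIORIZED	FALSE
del_i	deletion	i	11	stiff_i	ANTERIORIZED	FALSE
inversion_sparing_anchor	split_inversion	spare_anchor	11	uniform	UNCHANGED	FALSE
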