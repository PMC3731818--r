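# Elasticity profiles for the preset manipulation scenarios: piecewise
# stiffness s(u) of the wild-type mouse HoxD fiber, u in Kbp from the
# anterior (3') end. The last segment of each profile extends indefinitely.
# Mutant-expression outcomes after anterior deletions hinge on unobserved
# local elastic properties of the chromatin fiber; each scenario therefore
# declares the profile realizing its observed case.
profile_ref	from_kbp	to_kbp	stiffness
uniform	0	Inf	1
stiff_del_i_8_10	0	47	1
stiff_del_i_8_10	47	73	2
stiff_del_i_8_10	73	Inf	1
soft_del_9_12	0	67	1
soft_del_9_12	67	88	0.1
soft_del_9_12	88	Inf	1
stiff_i	0	47	1
stiff_i	47	57	2
stiff_i	57	Inf	1
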