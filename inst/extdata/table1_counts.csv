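variable,group,numerator,denominator
male,healthy,12,17
male,resolving,31,41
male,non_resolving,78,101
male,early_nonsurvivor,36,51
white,resolving,35,41
white,non_resolving,89,101
white,early_nonsurvivor,48,51
tbi,resolving,14,41
tbi,non_resolving,66,101
tbi,early_nonsurvivor,29,51
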