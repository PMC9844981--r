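characteristic	level	n_low_risk	n_unsafe
gender	male	151	240
gender	female	51	153
gender	transgender	2	2
incarceration	no	148	279
incarceration	yes	52	113
education	less_than_high_school	74	156
education	high_school_and_up	129	236
ever_tested	yes	60	110
ever_tested	no	141	280
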