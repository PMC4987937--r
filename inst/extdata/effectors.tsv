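# Effector presets: PAM pattern, anchor side relative to the protospacer,
# default spacer length (nt) and modeled cut offset (bp from the
# PAM-proximal protospacer end, measured into the protospacer).
# Values follow each effector's primary characterization literature and
# are user-overridable (copy this file and pass it to effectorPresets()).
name	pam	anchor	guide_length	cut_offset
SpCas9	NGG	3prime	20	3
StCas9	NNAGAAW	3prime	20	3
SaCas9	NNGRRT	3prime	21	3
NmCas9	NNNNGATT	3prime	24	3
AsCpf1	TTTN	5prime	20	18
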