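# name=example-identity
# window=4,20,3,3
# link=identity
# intercept=0.5
# ---------------------------------------------------------------
# Illustrative position-feature model demonstrating the file
# format (offset<TAB>kmer<TAB>weight; offsets are 1-based within
# the 30-bp context window upstream|guide|PAM|downstream).  The
# weights are synthetic examples, NOT published coefficients;
# drop in a published table in this format to use a real model.
# ---------------------------------------------------------------
1	A	0.10
5	G	0.15
24	G	0.20
20	GG	-0.25
28	C	0.05
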