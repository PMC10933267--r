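# 9aaTAD search patterns: per-position allowed amino acids over the
# 9-residue window. Reconstructed from the published position rules of the
# in silico 9aaTAD prediction tool; edit freely - the scanner treats this
# file as data. Positions p3/p4 and p6/p7 are the bulky hydrophobic core;
# p2 and p9 favour acidic/polar anchor residues; internal prolines are
# disallowed at p5/p8 in the moderate pattern.

[moderate]
stringency = moderate
p1 = DENQSTILVFWMYA
p2 = DENQSTKR
p3 = ILVFWMY
p4 = ILVFWMYA
p5 = ACDEFGHIKLMNQRSTVWY
p6 = ILVFWMYA
p7 = DEILVFWMY
p8 = ACDEFGHIKLMNQRSTVWY
p9 = DENQSTILVFWMY

[low]
stringency = low
p1 = ACDEFGHIKLMNPQRSTVWY
p2 = ACDEFGHIKLMNPQRSTVWY
p3 = ILVFWMYA
p4 = ILVFWMYA
p5 = ACDEFGHIKLMNPQRSTVWY
p6 = ILVFWMYA
p7 = DEILVFWMYA
p8 = ACDEFGHIKLMNPQRSTVWY
p9 = ACDEFGHIKLMNPQRSTVWY
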