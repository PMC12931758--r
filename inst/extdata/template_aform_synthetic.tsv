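# Synthetic idealized local three-atom nucleotide template (Angstrom).
# Generated parametrically to reproduce typical A-form helix intra-nucleotide
# distances (P-C4' ~5.6, C4'-N ~3.9, P-N ~6.3); NOT extracted from any
# deposited structure. Rows: P, C4', glycosidic N; centered on the atom
# centroid. One template is shared across A/C/G/U.
atom	x	y	z
P	-3.2667	-1.8333	-0.3000
C4'	0.4333	2.3667	-0.3000
N	2.8333	-0.5333	0.6000

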