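# Assigned main-chain NOE contacts (HN and/or HA nuclei) of 6 M
# urea-denatured TC5b, transcribed from the published connectivity table.
# Sequential markers sit at residues 1-8 and 12-13 (the 12->13 contact is
# HA-based since Pro 12 has no backbone amide); side-chain->HN (i,i+2)
# contacts at residues 1, 4, 5, 6, 7, 12 (the partner side-chain proton is
# not resolved in the published table; a representative side-chain atom
# name is used); HA->HN (i,i+2) contacts at residues 4, 5, 14; and two
# HA->HN (i,i+3) contacts at residues 4 and 5. HN-HN (i,i+2) contacts are
# entirely absent.
res_i	atom_i	res_j	atom_j	peak_id
1	HN	2	HN	.
2	HN	3	HN	.
3	HN	4	HN	.
4	HN	5	HN	.
5	HN	6	HN	.
6	HN	7	HN	.
7	HN	8	HN	.
8	HN	9	HN	.
12	HA	13	HN	.
13	HN	14	HN	.
1	HB	3	HN	.
4	HG2	6	HN	.
5	HB	7	HN	.
6	HB	8	HN	.
7	HB	9	HN	.
12	HB	14	HN	.
4	HA	6	HN	.
5	HA	7	HN	.
14	HA	16	HN	.
4	HA	7	HN	.
5	HA	8	HN	.
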