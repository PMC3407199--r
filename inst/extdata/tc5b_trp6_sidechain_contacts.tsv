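# Inter-residue NOE contacts between the Trp 6 side chain and aliphatic
# side chains of 6 M urea-denatured TC5b (all-trans proline isomer),
# transcribed from the published side-chain contact table. peak_id carries
# the published cross-peak numbering where given.
res_i	atom_i	res_j	atom_j	peak_id
6	HB2	5	HB	.
6	HB2	7	HB	.
6	HB2	18	HD3	.
6	HB2	19	HD2	.
6	HD1	4	HG2	11
6	HD1	7	HD2	12
6	HD1	16	HG	13
6	HE3	4	HD1	5
6	HE3	4	HG2	1
6	HE3	4	HG2	4
6	HE3	7	HB	6
6	HE3	7	HD2	5
6	HE3	7	HG	7
6	HE3	16	HD	3
6	HE3	16	HG	2
6	HH2	4	HD1	9
6	HH2	7	HD2	9
6	HH2	16	HG	10
6	HZ2	4	HD1	14
6	HZ2	7	HD2	14
6	HZ2	12	HD2	8
6	HZ3	12	HD3	8
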