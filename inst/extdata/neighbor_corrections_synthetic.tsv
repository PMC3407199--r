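# SYNTHETIC neighbour-correction increments (ppm) for sequence-corrected
# random-coil referencing. The offsets follow the package convention:
# offset is the neighbour's position relative to the residue being
# corrected (-2, -1, +1, +2). Magnitudes are representative of the two
# dominant real effects (a following proline and flanking glycines); they
# are illustrative values for testing, not a published calibration.
neighbor_type	offset	nucleus	delta_ppm
P	1	CA	-2.0
P	1	CB	-0.2
P	1	C	-0.6
P	-1	CA	0.1
G	1	CA	-0.1
G	1	C	0.2
G	-1	CA	-0.1
G	-1	C	-0.2
G	2	C	0.1
G	-2	C	0.1
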