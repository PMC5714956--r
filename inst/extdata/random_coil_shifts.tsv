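# Random-coil chemical shifts (ppm) and fully-formed secondary-structure
# secondary-shift magnitudes (ppm), per residue type, plus random-coil
# 3J(HN-HA) couplings (Hz). Representative literature-style values suitable
# for intrinsically disordered peptides; version 1 of the packaged table.
# NA: atom absent (Gly CB) or not applicable (Pro amide).
res	rc_CA	rc_CB	rc_HA	rc_HN	rc_N	helix_CA	helix_CB	helix_HA	strand_CA	strand_CB	strand_HA	rc_J3
A	52.5	19.1	4.32	8.24	123.8	3.1	-0.5	-0.38	-1.5	2.2	0.38	6.1
R	56.0	30.9	4.34	8.23	120.5	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.0
N	53.1	38.9	4.74	8.40	118.7	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.2
D	54.2	41.1	4.64	8.34	120.4	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.2
C	58.2	28.0	4.55	8.32	118.8	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.1
Q	55.7	29.4	4.34	8.32	119.8	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.0
E	56.6	30.0	4.35	8.42	120.2	3.1	-0.5	-0.38	-1.5	2.2	0.38	6.9
G	45.1	NA	3.96	8.33	108.8	3.1	NA	-0.38	-1.5	NA	0.38	6.4
H	55.0	29.0	4.73	8.42	118.2	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.3
I	61.1	38.8	4.17	8.00	119.9	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.5
L	55.1	42.4	4.34	8.16	121.8	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.0
K	56.2	33.1	4.32	8.29	120.4	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.0
M	55.4	32.9	4.48	8.28	119.6	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.1
F	57.7	39.6	4.62	8.30	120.3	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.3
P	63.3	32.1	4.42	NA	NA	3.1	-0.5	-0.38	-1.5	2.2	0.38	NA
S	58.3	63.8	4.47	8.31	115.7	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.0
T	61.8	69.8	4.35	8.15	113.6	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.5
W	57.5	29.6	4.66	8.25	121.3	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.2
Y	57.9	38.8	4.55	8.12	120.3	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.3
V	62.2	32.9	4.12	8.03	119.2	3.1	-0.5	-0.38	-1.5	2.2	0.38	7.6
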