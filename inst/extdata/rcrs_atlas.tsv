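# rCRS (NC_012920.1) region atlas, 1-based inclusive coordinates, genome length 16569.
# Intervals with start > end wrap through the origin (16569 -> 1).
# Top-level partition: CR + gene/rRNA/tRNA + non_coding covers every position once.
# Gene loci follow the MITOMAP GenomeLoci convention; three pairs of genuinely
# overlapping loci are trimmed so that per-position gene assignment is unique:
#   MT-TQ 4329-4400 -> 4332-4400 (3' end of MT-TI kept)
#   MT-ATP8 8366-8572 -> 8366-8526 (overlap assigned to MT-ATP6)
#   MT-ND4L 10470-10766 -> 10470-10759 (overlap assigned to MT-ND4)
# HV spans follow the MITOMAP convention. Control-region functional domains and
# secondary-structure elements other than ETAS2 (16294-16357), K (181-226) and
# J (116-149) are editable reconstructions from the cited locus sources, not
# values printed in any single study; see the package vignette.
label	category	start	end
CR	CR	16024	576
MT-TF	tRNA	577	647
MT-RNR1	rRNA	648	1601
MT-TV	tRNA	1602	1670
MT-RNR2	rRNA	1671	3229
MT-TL1	tRNA	3230	3304
NC_3305	non_coding	3305	3306
MT-ND1	gene	3307	4262
MT-TI	tRNA	4263	4331
MT-TQ	tRNA	4332	4400
NC_4401	non_coding	4401	4401
MT-TM	tRNA	4402	4469
MT-ND2	gene	4470	5511
MT-TW	tRNA	5512	5579
NC_5580	non_coding	5580	5586
MT-TA	tRNA	5587	5655
NC_5656	non_coding	5656	5656
MT-TN	tRNA	5657	5729
NC_5730	non_coding	5730	5760
MT-TC	tRNA	5761	5826
MT-TY	tRNA	5827	5891
NC_5892	non_coding	5892	5903
MT-CO1	gene	5904	7445
MT-TS1	tRNA	7446	7514
NC_7515	non_coding	7515	7517
MT-TD	tRNA	7518	7585
MT-CO2	gene	7586	8269
NC_8270	non_coding	8270	8294
MT-TK	tRNA	8295	8364
NC_8365	non_coding	8365	8365
MT-ATP8	gene	8366	8526
MT-ATP6	gene	8527	9207
MT-CO3	gene	9208	9990
MT-TG	tRNA	9991	10058
MT-ND3	gene	10059	10404
MT-TR	tRNA	10405	10469
MT-ND4L	gene	10470	10759
MT-ND4	gene	10760	12137
MT-TH	tRNA	12138	12206
MT-TS2	tRNA	12207	12265
MT-TL2	tRNA	12266	12336
MT-ND5	gene	12337	14148
MT-ND6	gene	14149	14673
MT-TE	tRNA	14674	14742
NC_14743	non_coding	14743	14746
MT-CYB	gene	14747	15887
MT-TT	tRNA	15888	15953
NC_15954	non_coding	15954	15955
MT-TP	tRNA	15956	16023
HV1	HV	16024	16383
HV2	HV	57	372
HV3	HV	438	574
ETAS1	functional_domain	16157	16172
ETAS2	functional_domain	16294	16357
CENTRAL_DOMAIN	functional_domain	16384	56
CSB1	functional_domain	213	235
CSB2	functional_domain	299	315
CSB3	functional_domain	346	363
LSP	functional_domain	392	445
A	structure_element	16079	16103
B	structure_element	16170	16193
C	structure_element	16294	16335
D	structure_element	16390	16420
E	structure_element	16445	16475
F	structure_element	16489	16510
G	structure_element	16528	16555
H	structure_element	37	59
I	structure_element	80	109
J	structure_element	116	149
K	structure_element	181	226
L	structure_element	240	266
M	structure_element	275	296
HP_66	homopolymer	66	71
HP_300	homopolymer	300	316
HP_513	homopolymer	513	525
HP_3106	homopolymer	3106	3107
HP_5892	homopolymer	5892	5892
HP_12418	homopolymer	12418	12425
HP_16182	homopolymer	16182	16194
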