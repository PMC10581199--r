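# residue_type atom_name mean std
A	N	123.2000	4.2000
A	H	8.3000	0.6000
A	CA	53.2000	1.9000
A	HA	4.3500	0.3200
A	C	176.4000	1.8000
A	CB	19.0000	1.9000
A	HB1	1.3900	0.3200
A	HB2	1.3900	0.3200
A	HB3	1.3900	0.3200
R	N	120.8000	4.2000
R	H	8.3000	0.6000
R	CA	56.8000	1.9000
R	HA	4.3500	0.3200
R	C	176.4000	1.8000
R	CB	30.7000	1.9000
R	CG	27.2000	1.9000
R	CD	43.2000	1.9000
R	CZ	159.5000	2.2000
R	NE	84.6000	2.0000
R	NH1	72.6000	2.0000
R	NH2	72.4000	2.0000
R	HB2	1.8200	0.3200
R	HB3	1.7800	0.3200
R	HG2	1.6200	0.3200
R	HG3	1.5800	0.3200
R	HD2	3.1700	0.3200
R	HD3	3.1300	0.3200
R	HE	7.3500	0.5000
N	N	118.9000	4.2000
N	H	8.3000	0.6000
N	CA	53.5000	1.9000
N	HA	4.3500	0.3200
N	C	176.4000	1.8000
N	CB	38.7000	1.9000
N	CG	176.8000	1.8000
N	ND2	112.8000	2.0000
N	HB2	2.8300	0.3200
N	HB3	2.7600	0.3200
N	HD21	7.3500	0.5000
N	HD22	7.1500	0.5000
D	N	120.4000	4.2000
D	H	8.3000	0.6000
D	CA	54.7000	1.9000
D	HA	4.3500	0.3200
D	C	176.4000	1.8000
D	CB	40.9000	1.9000
D	CG	179.5000	1.8000
D	HB2	2.7300	0.3200
D	HB3	2.6600	0.3200
C	N	119.0000	4.2000
C	H	8.3000	0.6000
C	CA	58.2000	1.9000
C	HA	4.3500	0.3200
C	C	176.4000	1.8000
C	CB	32.8000	1.9000
C	HB2	2.9800	0.3200
C	HB3	2.9200	0.3200
E	N	120.7000	4.2000
E	H	8.3000	0.6000
E	CA	57.4000	1.9000
E	HA	4.3500	0.3200
E	C	176.4000	1.8000
E	CB	30.0000	1.9000
E	CG	36.1000	1.9000
E	CD	183.5000	1.8000
E	HB2	2.0500	0.3200
E	HB3	2.0100	0.3200
E	HG2	2.3000	0.3200
E	HG3	2.2700	0.3200
Q	N	119.9000	4.2000
Q	H	8.3000	0.6000
Q	CA	56.6000	1.9000
Q	HA	4.3500	0.3200
Q	C	176.4000	1.8000
Q	CB	29.2000	1.9000
Q	CG	33.7000	1.9000
Q	CD	179.7000	1.8000
Q	NE2	111.9000	2.0000
Q	HB2	2.1000	0.3200
Q	HB3	2.0500	0.3200
Q	HG2	2.3400	0.3200
Q	HG3	2.3100	0.3200
Q	HE21	7.3000	0.5000
Q	HE22	7.0000	0.5000
G	N	109.5000	4.2000
G	H	8.3000	0.6000
G	CA	45.4000	1.9000
G	HA2	3.9500	0.3200
G	HA3	3.9000	0.3200
G	C	174.0000	1.8000
H	N	119.1000	4.2000
H	H	8.3000	0.6000
H	CA	56.5000	1.9000
H	HA	4.3500	0.3200
H	C	176.4000	1.8000
H	CB	30.2000	1.9000
H	CG	131.0000	2.2000
H	CD2	119.5000	2.2000
H	CE1	136.5000	2.2000
H	ND1	195.0000	12.0000
H	NE2	180.0000	12.0000
H	HB2	3.1400	0.3200
H	HB3	3.0700	0.3200
H	HD2	7.0800	0.5000
H	HE1	8.1000	0.5000
I	N	121.4000	4.2000
I	H	8.3000	0.6000
I	CA	61.6000	1.9000
I	HA	4.3500	0.3200
I	C	176.4000	1.8000
I	CB	38.6000	1.9000
I	CG1	27.7000	1.9000
I	CG2	17.5000	1.9000
I	CD1	13.4000	1.9000
I	HB	1.7800	0.3200
I	HG12	1.2800	0.3200
I	HG13	1.2000	0.3200
I	HG21	0.8600	0.3200
I	HG22	0.8600	0.3200
I	HG23	0.8600	0.3200
I	HD11	0.8000	0.3200
I	HD12	0.8000	0.3200
I	HD13	0.8000	0.3200
L	N	121.8000	4.2000
L	H	8.3000	0.6000
L	CA	55.6000	1.9000
L	HA	4.3500	0.3200
L	C	176.4000	1.8000
L	CB	42.3000	1.9000
L	CG	26.8000	1.9000
L	CD1	24.7000	1.9000
L	CD2	24.1000	1.9000
L	HB2	1.6400	0.3200
L	HB3	1.5500	0.3200
L	HG	1.6000	0.3200
L	HD11	0.8500	0.3200
L	HD12	0.8500	0.3200
L	HD13	0.8500	0.3200
L	HD21	0.8200	0.3200
L	HD22	0.8200	0.3200
L	HD23	0.8200	0.3200
K	N	121.3000	4.2000
K	H	8.3000	0.6000
K	CA	56.9000	1.9000
K	HA	4.3500	0.3200
K	C	176.4000	1.8000
K	CB	32.8000	1.9000
K	CG	24.9000	1.9000
K	CD	29.0000	1.9000
K	CE	41.9000	1.9000
K	NZ	33.2000	2.0000
K	HB2	1.8000	0.3200
K	HB3	1.7500	0.3200
K	HG2	1.4300	0.3200
K	HG3	1.3900	0.3200
K	HD2	1.6800	0.3200
K	HD3	1.6600	0.3200
K	HE2	2.9900	0.3200
K	HE3	2.9700	0.3200
M	N	120.1000	4.2000
M	H	8.3000	0.6000
M	CA	56.1000	1.9000
M	HA	4.3500	0.3200
M	C	176.4000	1.8000
M	CB	32.9000	1.9000
M	CG	32.0000	1.9000
M	CE	17.1000	1.9000
M	HB2	2.0600	0.3200
M	HB3	2.0000	0.3200
M	HG2	2.5800	0.3200
M	HG3	2.5200	0.3200
M	HE1	2.0200	0.3200
M	HE2	2.0200	0.3200
M	HE3	2.0200	0.3200
F	N	120.3000	4.2000
F	H	8.3000	0.6000
F	CA	58.1000	1.9000
F	HA	4.3500	0.3200
F	C	176.4000	1.8000
F	CB	39.9000	1.9000
F	CG	138.5000	2.2000
F	CD1	131.5000	2.2000
F	CD2	131.4000	2.2000
F	CE1	130.7000	2.2000
F	CE2	130.7000	2.2000
F	CZ	129.2000	2.2000
F	HB2	3.0400	0.3200
F	HB3	2.9700	0.3200
F	HD1	7.2200	0.5000
F	HD2	7.2200	0.5000
F	HE1	7.3400	0.5000
F	HE2	7.3400	0.5000
F	HZ	7.2800	0.5000
P	N	132.0000	4.2000
P	CA	63.3000	1.9000
P	HA	4.3500	0.3200
P	C	176.4000	1.8000
P	CB	31.8000	1.9000
P	CG	27.2000	1.9000
P	CD	50.3000	1.9000
P	HB2	2.0800	0.3200
P	HB3	2.0100	0.3200
P	HG2	1.9600	0.3200
P	HG3	1.9200	0.3200
P	HD2	3.6500	0.3200
P	HD3	3.6000	0.3200
S	N	116.3000	4.2000
S	H	8.3000	0.6000
S	CA	58.7000	1.9000
S	HA	4.3500	0.3200
S	C	176.4000	1.8000
S	CB	63.8000	1.9000
S	HB2	3.8900	0.3200
S	HB3	3.8500	0.3200
T	N	114.6000	4.2000
T	H	8.3000	0.6000
T	CA	62.2000	1.9000
T	HA	4.3500	0.3200
T	C	176.4000	1.8000
T	CB	69.7000	1.9000
T	CG2	21.4000	1.9000
T	HB	4.1700	0.3200
T	HG21	1.2000	0.3200
T	HG22	1.2000	0.3200
T	HG23	1.2000	0.3200
W	N	121.7000	4.2000
W	H	8.3000	0.6000
W	CA	57.7000	1.9000
W	HA	4.3500	0.3200
W	C	176.4000	1.8000
W	CB	29.9000	1.9000
W	CG	110.5000	2.2000
W	CD1	126.5000	2.2000
W	CD2	127.5000	2.2000
W	CE2	138.0000	2.2000
W	CE3	120.5000	2.2000
W	CZ2	114.3000	2.2000
W	CZ3	121.5000	2.2000
W	CH2	123.8000	2.2000
W	NE1	129.3000	2.0000
W	HB2	3.2400	0.3200
W	HB3	3.1700	0.3200
W	HD1	7.2200	0.5000
W	HE1	10.1000	0.5000
W	HE3	7.5500	0.5000
W	HZ2	7.4500	0.5000
W	HZ3	7.1000	0.5000
W	HH2	7.1500	0.5000
Y	N	120.5000	4.2000
Y	H	8.3000	0.6000
Y	CA	58.1000	1.9000
Y	HA	4.3500	0.3200
Y	C	176.4000	1.8000
Y	CB	39.0000	1.9000
Y	CG	129.8000	2.2000
Y	CD1	132.8000	2.2000
Y	CD2	132.8000	2.2000
Y	CE1	118.0000	2.2000
Y	CE2	118.0000	2.2000
Y	CZ	156.7000	2.2000
Y	HB2	2.9800	0.3200
Y	HB3	2.9000	0.3200
Y	HD1	7.0500	0.5000
Y	HD2	7.0500	0.5000
Y	HE1	6.7500	0.5000
Y	HE2	6.7500	0.5000
V	N	121.1000	4.2000
V	H	8.3000	0.6000
V	CA	62.5000	1.9000
V	HA	4.3500	0.3200
V	C	176.4000	1.8000
V	CB	32.6000	1.9000
V	CG1	21.5000	1.9000
V	CG2	21.3000	1.9000
V	HB	2.0600	0.3200
V	HG11	0.9200	0.3200
V	HG12	0.9200	0.3200
V	HG13	0.9200	0.3200
V	HG21	0.9000	0.3200
V	HG22	0.9000	0.3200
V	HG23	0.9000	0.3200
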