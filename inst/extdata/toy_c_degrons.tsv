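motif	dpsi	source_id
EGG	-0.95	SYN_C01
RGG	-0.88	SYN_C02
GGD	-0.82	SYN_C03
VGG	-0.74	SYN_C04
EEN	-0.66	SYN_C05
GG	-0.60	SYN_C06
EE	-0.52	SYN_C07
RA	-0.35	SYN_C08
SS	-0.05	SYN_C09
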