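motif	dpsi	source_id
DEG	-0.90	SYN_N01
EED	-0.85	SYN_N02
NKD	-0.80	SYN_N03
DDW	-0.75	SYN_N04
EEV	-0.70	SYN_N05
GG	-0.55	SYN_N06
AK	-0.45	SYN_N07
PL	-0.30	SYN_N08
QQ	-0.10	SYN_N09
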