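character	MESO	CHLO	PCUS	PRMA	MBIC	PYRA	MONO	MICR	OSTR	NAST	NOLI	PYCN	PICO	CCMP1205
ndhJ	1	1	1	1	0	0	0	0	0	0	0	0	0	0
rbcR	1	1	1	1	1	0	0	0	0	0	0	0	0	0
rpl21	1	1	1	1	1	0	0	0	0	0	0	0	0	0
rps15	1	1	1	1	1	0	0	0	0	0	0	0	0	0
rps16	1	1	1	1	1	0	0	0	0	0	0	0	0	0
ycf66	1	1	1	1	1	0	0	0	0	0	0	0	0	0
IR	1	1	0	0	0	1	0	1	1	1	1	0	1	0
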