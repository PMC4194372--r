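synonym	canonical
ycf9	psbZ
psbZ	psbZ
rrn16	rrs
rrn16S	rrs
16S	rrs
16S rRNA	rrs
rrnS	rrs
rrn23	rrl
rrn23S	rrl
23S	rrl
23S rRNA	rrl
rrnL	rrl
rrn5	rrf
rrn5S	rrf
5S	rrf
5S rRNA	rrf
rrn5.8	rrf
trnfM-cau	trnMf-cau
trnfM	trnMf-cau
trnM-cau	trnMe-cau
ycf3a	ycf3a
ycf3b	ycf3b
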