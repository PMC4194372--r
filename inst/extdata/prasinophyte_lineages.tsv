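taxon	lineage	group
PCUS	cladeVI	prasinophyte
PRMA	cladeVI	prasinophyte
MBIC	cladeVI	prasinophyte
PYRA	cladeI	prasinophyte
MICR	cladeII	prasinophyte
MONO	cladeII	prasinophyte
OSTR	cladeII	prasinophyte
NAST	cladeIII	prasinophyte
NOLI	cladeIII	prasinophyte
PYCN	cladeV	prasinophyte
PICO	cladeVIIC	prasinophyte
CCMP1205	cladeVIIA	prasinophyte
MESO	streptophyte	outgroup
CHLO	streptophyte	outgroup
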