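locus_id	class	allele_A	allele_B
mt_sp01	species	A	G
mt_sp02	species	G	A
mt_sp03	species	T	C
mt_sp04	species	C	T
mt_sp05	species	A	G
mt_sp06	species	G	A
mt_sp07	species	T	C
mt_sp08	species	C	T
mt_sp09	species	A	G
mt_sp10	species	G	A
mt_cl01	clade	C	T
mt_cl02	clade	T	C
mt_cl03	clade	A	G
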