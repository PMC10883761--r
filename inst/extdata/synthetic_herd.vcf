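##fileformat=VCFv4.2
##source=bisonpanel
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	pop1_f001	pop1_f002	pop1_f003	pop1_f004	pop1_f005	pop1_f006	pop1_f007	pop1_f008	pop2_f001	pop2_f002	pop2_f003	pop2_f004	pop2_f005	pop2_f006	pop2_f007	pop2_f008
chr6	54867042	snp0001	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/0	0/1	0/1	0/0	1/1	0/1	0/1	0/0	0/0
chr6	59137031	snp0002	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
chr10	11962667	snp0003	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/0	1/1	1/1	0/1	0/1	0/0	0/1	0/1	0/1
chr12	65193267	snp0004	A	G	.	PASS	.	GT	0/0	0/0	1/1	0/1	0/0	0/0	0/0	1/1	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/1
chr14	29854866	snp0005	A	G	.	PASS	.	GT	0/0	0/0	./.	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/1	0/1	0/1
chr16	71545342	snp0006	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/1	./.	1/1	0/1	1/1	0/0	./.	0/1	1/1	0/0	0/1	0/1	1/1
chr19	62074416	snp0007	A	G	.	PASS	.	GT	0/1	1/1	0/1	0/1	0/1	0/1	0/1	1/1	0/1	1/1	0/0	0/1	0/0	0/0	0/0	0/1
chr22	18873685	snp0008	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1
chr23	22697127	snp0009	A	G	.	PASS	.	GT	0/0	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0
chr23	63609460	snp0010	A	G	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr25	39597357	snp0011	A	G	.	PASS	.	GT	0/0	0/0	1/1	0/0	0/1	0/0	0/0	0/0	1/1	0/1	1/1	0/1	0/1	1/1	1/1	1/1
chr26	47987799	snp0012	A	G	.	PASS	.	GT	1/1	0/1	0/0	1/1	0/0	0/0	1/1	1/1	0/0	./.	0/0	0/1	0/0	0/0	0/0	./.
MT	1000	mt_sp01	G	A	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	1500	mt_sp02	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	2000	mt_sp03	C	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	2500	mt_sp04	T	C	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	3000	mt_sp05	G	A	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	3500	mt_sp06	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	4000	mt_sp07	C	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	4500	mt_sp08	T	C	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	5000	mt_sp09	G	A	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	5500	mt_sp10	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
MT	9000	mt_cl01	T	C	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1
MT	9500	mt_cl02	C	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	0/0	1/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	1/1
MT	10000	mt_cl03	G	A	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1
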