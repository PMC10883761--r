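sample_id	population_id	dam_id	sire_id
pop1_f001	pop1	NA	NA
pop1_f002	pop1	NA	NA
pop1_f003	pop1	NA	NA
pop1_f004	pop1	NA	NA
pop1_f005	pop1	NA	NA
pop1_f006	pop1	NA	NA
pop1_f007	pop1	NA	NA
pop1_f008	pop1	NA	NA
pop2_f001	pop2	NA	NA
pop2_f002	pop2	NA	NA
pop2_f003	pop2	NA	NA
pop2_f004	pop2	NA	NA
pop2_f005	pop2	NA	NA
pop2_f006	pop2	NA	NA
pop2_f007	pop2	NA	NA
pop2_f008	pop2	NA	NA
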