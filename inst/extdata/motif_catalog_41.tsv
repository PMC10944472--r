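motif_id	sequence	source_organism	known_function
Prz1	GCTGCGCCAC	S. pombe	activating
Zic3	CCCCCCGCTG	mouse	activating
bHLH	GTCACGTGAC	mouse/yeast	dual
Stp	CGGCGCTAGC	S. cerevisiae	activating
Abf1	TCACTCACTACGA	S. cerevisiae	activating
Nfi	GGGAACACTTCCC	mouse	activating
Reb1	TCCGGGTAAC	S. cerevisiae	dual
Ctcf	ACGCCCCCTA	mouse	dual
Rap1_sp	ACCCAKACACC	S. pombe	dual
Rap1_sc	AMACCCACACMCC	S. cerevisiae	dual
Yap	GCTTACGTCAGC	S. cerevisiae	dual
GAGGCGCAGC	GAGGCGCAGC	S. cerevisiae	unknown
ACAACAACAA	ACAACAACAA	D. melanogaster	unknown
GCTAAGCCAC	GCTAAGCCAC	S. pombe	unknown
ATGTCAATCA	ATGTCAATCA	mouse	unknown
syn01	GKGATAGCGTCC	synthetic	unknown
syn02	GGCCMGATGTG	synthetic	unknown
syn03	ACCCCTCCCM	synthetic	unknown
syn04	TCATTTKAGTA	synthetic	repressing
syn05	GTGCTATGTTKT	synthetic	activating
syn06	TATCTGACKGA	synthetic	activating
syn07	ATGAGMCCCGAG	synthetic	activating
syn08	GATMTACACGCA	synthetic	activating
syn09	AMACMACGGT	synthetic	repressing
syn10	ATCCTMGAAKTA	synthetic	unknown
syn11	GGTCCMTCGKAT	synthetic	activating
syn12	GMGMTGATAA	synthetic	repressing
syn13	AGCCCTACGGKM	synthetic	unknown
syn14	GTCGKMTAAGTC	synthetic	repressing
syn15	GKGAATGGKK	synthetic	unknown
syn16	TCMCCAMTKTT	synthetic	repressing
syn17	GCKKAKGMTG	synthetic	repressing
syn18	MGATCAMKCCMC	synthetic	unknown
syn19	TTGATTTACCC	synthetic	unknown
syn20	CCTCTAGACCCT	synthetic	activating
syn21	CACACTAACTTTC	synthetic	repressing
syn22	CCCAGAGTAATTC	synthetic	repressing
syn23	CTCATCTGTTAA	synthetic	activating
syn24	AGGTATCAACAC	synthetic	repressing
syn25	GGTACTACTGAT	synthetic	repressing
syn26	TTCCTGTACGTCA	synthetic	unknown
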