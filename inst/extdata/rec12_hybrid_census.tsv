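# Transcribed observed counts: viable spores genotyped from rec12-null
# Sk/Sp hybrid meioses (wet-lab census; used as printed inputs, not
# regenerated by the model).
class	count
K1K2K3_P3_aneuploid	289
K1K2K3_haploid	38
all_viable_genotyped	589
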