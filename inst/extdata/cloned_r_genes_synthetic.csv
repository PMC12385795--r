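# SYNTHETIC STAND-IN catalogue of 49 cloned R genes.
# Entries named in the source literature keep their reported disease
# associations; Syn_R* rows are synthetic placeholders added to reach the
# published catalogue size of 49. Disease codes: ABS, BL, BLS, BR, CR, DM,
# FW, GM, HR, PM, SSR, WR. Diseases are semicolon-separated.
r_gene_id,diseases
At_WRR9,WR
At_WRR4a,WR
At_WRR4b,WR
At_WRR12,WR
At_RAC1,WR
At_NGR1a,WR
At_NGR1b,DM
Bju_WRR1,WR
At_RPP1,DM
At_RPP2a,DM
At_RPP2b,DM
At_RPP4,DM
At_RPP7,DM
At_RPP8,DM
At_RPP13,DM
At_RLM1a,BL
At_RLM1b,BL
Bna_Rlm9/4/7,BL
Bna_LepR3/Rlm2,BL
Bra_Crr1a,CR
Bra_cRa/cRb,CR
At_Rpw8.1,PM
Syn_R23,ABS
Syn_R24,BL
Syn_R25,BLS
Syn_R26,BR
Syn_R27,CR
Syn_R28,DM
Syn_R29,FW
Syn_R30,GM
Syn_R31,PM
Syn_R32,SSR
Syn_R33,WR
Syn_R34,ABS;BL
Syn_R35,BL
Syn_R36,BLS
Syn_R37,CR
Syn_R38,DM
Syn_R39,FW
Syn_R40,GM
Syn_R41,PM
Syn_R42,SSR
Syn_R43,WR
Syn_R44,BL;SSR
Syn_R45,DM;WR
Syn_R46,CR
Syn_R47,GM
Syn_R48,PM
Syn_R49,SSR
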