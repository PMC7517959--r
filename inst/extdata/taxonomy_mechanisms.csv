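code,label,parent
immune,Immune system,
checkpoint,Checkpoint inhibitor,immune
adoptive_cell,Adoptive cell transfer,immune
t_cell,Adoptive cell: T cell,adoptive_cell
adoptive_other,Adoptive cell: other,adoptive_cell
oncolytic_virus,Oncolytic virus,immune
vaccine,Cancer vaccine,immune
other_immune,Other immune or cytokine,immune
dna_cell_cycle,DNA and cell cycle,
cell_signaling,Cell signaling,
rtk,Receptor tyrosine kinases,cell_signaling
ras_raf_mek_erk,KRAS/RAF/MEK/ERK,cell_signaling
pi3k_akt_mtor,PI3K/AKT/mTOR,cell_signaling
jak_stat,JAK-STAT,cell_signaling
fak_src,FAK/SRC,cell_signaling
signaling_misc,Misc. signaling (HH WNT Hsp90 GSK-3 TGFbeta),cell_signaling
metabolism,Metabolism,
angiogenesis,Angiogenesis,
hormone_receptor,Hormone receptors,
apoptosis,Apoptosis specific,
symptom,Target symptoms,
thrombosis,Anti-thrombosis,symptom
infection,Anti-infection,symptom
enzyme_supplementation,Digestive enzyme supplementation,symptom
metastasis_invasion,Metastasis and invasion,
unknown,Unknown mechanism,
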