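code,label,parent
drug,Novel drug or pharmacologic agent,
small_molecule,Small molecule,drug
monoclonal_antibody,Monoclonal antibody,drug
other_pharma,Other pharmacologic agent,drug
conventional,Conventional or existing therapy,
pdac_combination_or_delivery,New combination or delivery of established PDAC drugs,conventional
fda_approved_other_cancer,FDA-approved therapy for other cancers,conventional
radiation,Radiation-based intervention,conventional
gene_therapy,Gene therapy,
cellular_therapy,Cellular therapy,
nutraceutical,Nutraceutical,
procedure,Technique or procedure,
pain_qol,Pain management or quality of life,
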