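criterion,criterion_label,level,level_label,points
novelty,Novelty,novel_mechanism_pdac,Novel therapeutic mechanism in PDAC,5
novelty,Novelty,novel_drug_or_indication_pdac,Novel drug or indication in PDAC,2
novelty,Novelty,beyond_standard_of_care,Any PDAC therapy beyond standard of care,1
novelty,Novelty,established,Established PDAC intervention,0
promise,Promise,phase3_success_other,Phase III success in other cancer type,2
promise,Promise,untested_or_under_investigation,Currently under investigation or untested in other cancers,0
promise,Promise,any_phase_failure_other,Any phase failure in other cancer type,-2
allocation,Allocation,randomized,Randomized,1
allocation,Allocation,not_applicable,Not applicable,0
allocation,Allocation,non_randomized,Non-randomized,-1
pfs,Progression Free Survival,gt6mo,Greater than 6-month improvement,2
pfs,Progression Free Survival,one_to_6mo,1-6-month improvement,1
pfs,Progression Free Survival,lt1mo,Less than 1-month improvement,0
os,Overall Survival,gt6mo,Greater than 6-month improvement,2
os,Overall Survival,one_to_6mo,1-6-month improvement,1
os,Overall Survival,lt1mo,Less than 1-month improvement,0
susceptibility,Expected percentage of pancreatic cancers susceptible,gt30pct,Applicable to more than 30 percent of PDAC tumors,3
susceptibility,Expected percentage of pancreatic cancers susceptible,pct5_to_30,Applicable to 5-30 percent of PDAC tumors,2
susceptibility,Expected percentage of pancreatic cancers susceptible,lt5pct,Applicable to less than 5 percent of PDAC tumors,1
impact,Desired impact,direct_treat,Directly treat PDAC,3
impact,Desired impact,procedural_or_sequencing,Procedural or sequencing modifications,1
impact,Desired impact,symptoms_or_sequelae,Mitigate symptoms or sequelae,0
status,Trial status,active,Active,0
status,Trial status,terminated_and_published,Terminated and published,-5
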