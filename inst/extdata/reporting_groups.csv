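class_id,drug_group
thiazide_diuretics,Diuretics
loop_diuretics,Diuretics
potassium_sparing_diuretics,Diuretics
ace_inhibitors,Agents acting on RAAS
arbs,Agents acting on RAAS
beta_blockers,Beta blocking agents
calcium_antagonists,Calcium channel blockers
alpha1_blockers,Antihypertensives
long_acting_nitrates,Cardiac therapy
digoxin,Cardiac therapy
antiarrhythmics,Cardiac therapy
benzodiazepines,Psycholeptics
antipsychotics,Psycholeptics
ssris,Psychoanaleptics
tcas,Psychoanaleptics
other_antidepressants,Psychoanaleptics
vitamin_k_antagonists,Antithrombotic agents
doacs,Antithrombotic agents
heparins,Antithrombotic agents
other_anticoagulants,Antithrombotic agents
platelet_inhibitors,Antithrombotic agents
nsaids,Antiinflammatory and antirheumatic drugs
opioids,Analgesics
oral_antidiabetics,Drugs used in diabetes
insulins,Drugs used in diabetes
systemic_corticosteroids,Corticosteroids for systemic use
antibiotics,Antibacterials for systemic use
anticholinergic_sedatives,Anticholinergic/sedative drugs
anti_parkinson_drugs,Anti-parkinson drugs
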