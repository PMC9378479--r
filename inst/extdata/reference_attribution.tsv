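trigger_id	drug_group	n_adr	n_pc
fall	Diuretics	17	4
fall	Beta blocking agents	17	2
fall	Agents acting on RAAS	17	0
fall	Psychoanaleptics	0	3
fall	Other	35	5
delirium	Analgesics	21	12
delirium	Psycholeptics	9	0
delirium	Psychoanaleptics	7	0
delirium	Antiepileptics	0	1
delirium	Anti-parkinson drugs	0	1
delirium	Cardiac therapy	0	1
delirium	Other	15	0
renal_insufficiency_dehydration	Diuretics	59	12
renal_insufficiency_dehydration	Agents acting on RAAS	27	9
renal_insufficiency_dehydration	Antiinflammatory and antirheumatic drugs	8	7
hyponatraemia	Diuretics	44	18
hyponatraemia	Psychoanaleptics	9	5
hyponatraemia	Agents acting on RAAS	5	1
constipation_ileus	Analgesics	23	13
constipation_ileus	Calcium channel blockers	1	0
other_bleeding	Antithrombotic agents	17	7
other_bleeding	Antiinflammatory and antirheumatic drugs	2	0
hypoglycaemia	Drugs used in diabetes	13	10
hypokalaemia	Diuretics	14	5
hyperkalaemia	Diuretics	5	2
hyperkalaemia	Agents acting on RAAS	4	1
supratherapeutic_inr	Antithrombotic agents	9	9
vomiting_diarrhoea	Antibacterials for systemic use	8	6
gastrointestinal_bleeding	Antithrombotic agents	6	4
hyperglycaemia	Corticosteroids for systemic use	1	1
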