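trigger_id	n_combinations	unclassifiable	unlikely	possible	probable	certain	mean_drugs	min_drugs	max_drugs
fall	305	0	219	72	14	0	3.1	1	8
delirium	226	7	167	37	12	3	2.3	1	6
renal_insufficiency_dehydration	152	1	57	66	27	1	1.8	1	4
hyponatraemia	127	3	66	34	21	3	1.8	1	4
constipation_ileus	35	1	10	11	7	6	1.3	1	2
other_bleeding	23	0	4	12	4	3	1.3	1	2
hypoglycaemia	17	0	4	3	8	2	1.7	1	2
hypokalaemia	14	0	0	9	4	1	1.0	1	1
hyperkalaemia	13	0	4	6	3	0	1.3	1	1
supratherapeutic_inr	9	0	0	0	8	1	1.0	1	1
vomiting_diarrhoea	9	0	1	2	4	2	1.0	1	1
gastrointestinal_bleeding	7	0	1	2	3	1	1.0	1	1
hyperglycaemia	2	0	1	0	1	0	1.0	1	2
fracture	1	0	1	0	0	0	1.0	1	1
acute_heart_failure	1	0	1	0	0	0	1.0	1	1
intracranial_bleeding	0	0	0	0	0	0	NA	NA	NA
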