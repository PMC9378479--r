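trigger_id	n_adr	recognised_pct	n_adr_pc	recognised_pct_pc
fall	86	66.3	14	100
delirium	52	75.0	15	93.3
renal_insufficiency_dehydration	94	89.4	28	96.4
hyponatraemia	58	96.6	24	95.8
constipation_ileus	24	91.7	13	92.3
other_bleeding	19	73.7	7	100
hypoglycaemia	13	100	10	100
hypokalaemia	14	92.9	5	100
hyperkalaemia	9	88.9	3	100
supratherapeutic_inr	9	100	9	100
vomiting_diarrhoea	8	87.5	6	100
gastrointestinal_bleeding	6	83.3	4	100
hyperglycaemia	1	100	1	100
fracture	0	NA	0	NA
acute_heart_failure	0	NA	0	NA
intracranial_bleeding	0	NA	0	NA
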