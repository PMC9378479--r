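# Default trigger-tool definition: the explicated ADR trigger tool of the
# Dutch geriatric guideline on polypharmacy optimisation, with drug classes
# pinned to ATC prefixes/codes. Edit a copy of this file to localise the tool.
#
# Schema:
#   name, version                      strings
#   drug_classes: list of {class_id, label, atc_prefixes, include_codes, exclude_codes}
#     - atc_prefixes: ATC prefixes (1-7 chars); a code belongs to the class
#       when its leading characters equal a prefix
#     - include_codes: full ATC codes always in the class
#     - exclude_codes: full ATC codes never in the class
#   triggers: list of {trigger_id, label, event_synonyms, drug_classes}
#     - event_synonyms: normalised event labels (case-insensitive exact match);
#       must be unique across triggers
#     - drug_classes: class_ids from the registry above
name: explicated-geriatric-adr-trigger-tool
version: "1.0"

drug_classes:
  - class_id: thiazide_diuretics
    label: thiazide diuretics
    atc_prefixes: [C03A]
  - class_id: loop_diuretics
    label: loop diuretics
    atc_prefixes: [C03C]
  - class_id: potassium_sparing_diuretics
    label: potassium-sparing diuretics
    atc_prefixes: [C03D, C03E]
  - class_id: ace_inhibitors
    label: ACE inhibitors
    atc_prefixes: [C09A, C09B]
  - class_id: arbs
    label: angiotensin II receptor blockers
    atc_prefixes: [C09C, C09D]
  - class_id: beta_blockers
    label: beta blockers
    atc_prefixes: [C07]
  - class_id: calcium_antagonists
    label: calcium antagonists
    atc_prefixes: [C08]
  - class_id: alpha1_blockers
    label: alpha-1 blockers
    atc_prefixes: [C02CA]
  - class_id: long_acting_nitrates
    label: long-acting nitrates
    atc_prefixes: [C01DA]
  - class_id: digoxin
    label: digitalis glycosides
    include_codes: [C01AA05]
  - class_id: antiarrhythmics
    label: class I and III antiarrhythmics
    atc_prefixes: [C01B]
  - class_id: benzodiazepines
    label: benzodiazepines and related hypnotics
    atc_prefixes: [N05BA, N05CD, N05CF]
  - class_id: antipsychotics
    label: antipsychotics
    atc_prefixes: [N05A]
  - class_id: ssris
    label: selective serotonin reuptake inhibitors
    atc_prefixes: [N06AB]
  - class_id: tcas
    label: tricyclic antidepressants
    atc_prefixes: [N06AA]
  - class_id: other_antidepressants
    label: other antidepressants (duloxetine, venlafaxine, mirtazapine)
    include_codes: [N06AX21, N06AX16, N06AX11]
  - class_id: vitamin_k_antagonists
    label: vitamin K antagonists
    atc_prefixes: [B01AA]
  - class_id: doacs
    label: direct oral anticoagulants
    atc_prefixes: [B01AF]
  - class_id: heparins
    label: heparins
    atc_prefixes: [B01AB]
  - class_id: other_anticoagulants
    label: other anticoagulants
    atc_prefixes: [B01AE, B01AX]
  - class_id: platelet_inhibitors
    label: thrombocyte aggregation inhibitors
    atc_prefixes: [B01AC]
  - class_id: nsaids
    label: NSAIDs
    atc_prefixes: [M01A]
  - class_id: opioids
    label: opioids
    atc_prefixes: [N02A]
  - class_id: oral_antidiabetics
    label: oral blood-glucose-lowering drugs
    atc_prefixes: [A10B]
  - class_id: insulins
    label: insulins and analogues
    atc_prefixes: [A10A]
  - class_id: systemic_corticosteroids
    label: systemic corticosteroids
    atc_prefixes: [H02AB]
  - class_id: antibiotics
    label: antibacterials for systemic use
    atc_prefixes: [J01]
  # User-replaceable default for "drugs with anticholinergic and sedative
  # properties": broad-brush prefixes from published anticholinergic/sedative
  # burden lists (opioids, antiepileptics, psycholeptics, antidepressants,
  # sedating antihistamines, urinary antispasmodics, belladonna alkaloids).
  - class_id: anticholinergic_sedatives
    label: drugs with anticholinergic or sedative properties
    atc_prefixes: [N02A, N03A, N05A, N05B, N05C, N06A, R06A, G04BD, A03BA, A03BB]
  - class_id: anti_parkinson_drugs
    label: anti-Parkinson drugs
    atc_prefixes: [N04]

triggers:
  - trigger_id: fracture
    label: fracture
    event_synonyms: [fracture, bone fracture, hip fracture]
    drug_classes: [systemic_corticosteroids]
  - trigger_id: fall
    label: fall/collapse/(orthostatic) hypotension/dizziness/syncope
    event_synonyms:
      [fall, collapse, hypotension, orthostatic hypotension, dizziness, syncope]
    drug_classes:
      [ace_inhibitors, arbs, calcium_antagonists, beta_blockers,
       thiazide_diuretics, loop_diuretics, potassium_sparing_diuretics,
       alpha1_blockers, long_acting_nitrates, digoxin, antiarrhythmics,
       benzodiazepines, antipsychotics, ssris, tcas, other_antidepressants]
  - trigger_id: gastrointestinal_bleeding
    label: gastrointestinal bleeding
    event_synonyms:
      [gastrointestinal bleeding, gi bleeding, melaena, haematemesis]
    drug_classes:
      [vitamin_k_antagonists, doacs, heparins, other_anticoagulants,
       platelet_inhibitors, nsaids]
  - trigger_id: intracranial_bleeding
    label: intracranial bleeding
    event_synonyms:
      [intracranial bleeding, intracranial haemorrhage, subdural haematoma]
    drug_classes:
      [vitamin_k_antagonists, doacs, heparins, other_anticoagulants,
       platelet_inhibitors, nsaids]
  - trigger_id: other_bleeding
    label: other bleedings
    event_synonyms:
      [bleeding, epistaxis, haematuria, rectal blood loss, haematoma]
    drug_classes:
      [vitamin_k_antagonists, doacs, heparins, other_anticoagulants,
       platelet_inhibitors, nsaids]
  - trigger_id: supratherapeutic_inr
    label: supratherapeutic INR
    event_synonyms:
      [supratherapeutic inr, inr above therapeutic range, elevated inr]
    drug_classes: [vitamin_k_antagonists]
  - trigger_id: hyponatraemia
    label: hyponatraemia
    event_synonyms: [hyponatraemia, hyponatremia]
    drug_classes:
      [thiazide_diuretics, loop_diuretics, potassium_sparing_diuretics,
       ace_inhibitors, arbs, ssris, tcas, other_antidepressants]
  - trigger_id: hypokalaemia
    label: hypokalaemia
    event_synonyms: [hypokalaemia, hypokalemia]
    drug_classes: [thiazide_diuretics, loop_diuretics]
  - trigger_id: hyperkalaemia
    label: hyperkalaemia
    event_synonyms: [hyperkalaemia, hyperkalemia]
    drug_classes: [potassium_sparing_diuretics, ace_inhibitors, arbs]
  - trigger_id: renal_insufficiency_dehydration
    label: renal insufficiency and/or dehydration
    event_synonyms:
      [renal insufficiency, renal failure, acute kidney injury, dehydration]
    drug_classes:
      [ace_inhibitors, arbs, nsaids, thiazide_diuretics, loop_diuretics,
       potassium_sparing_diuretics]
  - trigger_id: hypoglycaemia
    label: hypoglycaemia
    event_synonyms: [hypoglycaemia, hypoglycemia]
    drug_classes: [oral_antidiabetics, insulins]
  - trigger_id: hyperglycaemia
    label: hyperglycaemia
    event_synonyms: [hyperglycaemia, hyperglycemia]
    drug_classes: [systemic_corticosteroids]
  - trigger_id: acute_heart_failure
    label: acute heart failure
    event_synonyms:
      [acute heart failure, heart failure, decompensated heart failure]
    drug_classes: [nsaids]
  - trigger_id: constipation_ileus
    label: constipation/ileus
    event_synonyms: [constipation, ileus]
    drug_classes: [opioids, calcium_antagonists]
  - trigger_id: vomiting_diarrhoea
    label: vomiting/diarrhoea
    event_synonyms: [vomiting, diarrhoea, diarrhea]
    drug_classes: [antibiotics]
  - trigger_id: delirium
    label: delirium/confusion/drowsiness
    event_synonyms: [delirium, confusion, drowsiness]
    drug_classes: [anticholinergic_sedatives, digoxin, anti_parkinson_drugs]
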