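# WHO-UMC causality decision table, shipped as editable data.
#
# Rules are evaluated top-down; the first category whose conditions all hold
# is returned, so the ordering encodes "highest category that qualifies".
#
# Condition semantics per rule:
#   when:    every listed field must take one of the listed values
#   any_of:  at least one of the listed field/value conditions must hold
#   unless:  the rule is vetoed when every listed field takes a listed value
# A rule with an empty `when` always matches (fallback).
#
# Evidence fields and their values:
#   temporal_relationship:       plausible | improbable | unknown
#   alternative_explanation:     excluded | unlikely | plausible | unknown
#   dechallenge:                 positive | negative | not_done | unknown
#   rechallenge:                 positive | negative | not_done
#   pharmacologically_definitive: true | false
#   data_sufficient:             true | false
rules:
  - category: unclassifiable
    when:
      data_sufficient: [false]
  - category: certain
    when:
      temporal_relationship: [plausible]
      alternative_explanation: [excluded]
      dechallenge: [positive]
    any_of:
      rechallenge: [positive]
      pharmacologically_definitive: [true]
  - category: probable
    when:
      temporal_relationship: [plausible]
      alternative_explanation: [excluded, unlikely]
      dechallenge: [positive]
  - category: possible
    when:
      temporal_relationship: [plausible]
    unless:
      alternative_explanation: [plausible]
      dechallenge: [negative]
  - category: unlikely
    when: {}
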