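# Default child cause hierarchy (rank 1 = top). Measles outranks pneumonia
# (pneumonia is likely a consequence of measles), malnutrition sits high so
# it can be identified as an underlying cause, diarrhea is above pneumonia,
# and every "possible" tier ranks strictly below its probable counterpart
# so that possible diagnoses only claim deaths the probable criteria leave
# unspecified. Other infections is the residual infectious rule and sits at
# the bottom, above unspecified only.
age_group: child
order:
  - {cause: injury, comorbid: false}
  - {cause: aids, comorbid: false}
  - {cause: malnutrition, comorbid: true}
  - {cause: measles, comorbid: false}
  - {cause: meningitis, comorbid: true}
  - {cause: dysentery, comorbid: true}
  - {cause: diarrhea, comorbid: true}
  - {cause: pertussis, comorbid: true}
  - {cause: pneumonia, comorbid: true}
  - {cause: malaria, comorbid: true}
  - {cause: hemorrhagic_fever, comorbid: true}
  - {cause: possible_dysentery, comorbid: true}
  - {cause: possible_diarrhea, comorbid: true}
  - {cause: possible_pneumonia, comorbid: true}
  - {cause: possible_malaria, comorbid: true}
  - {cause: other_infections, comorbid: true}
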