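# Minimal diagnostic criteria for child causes (1-59 months). Documented
# floors: pneumonia requires at least difficult or fast breathing;
# meningitis requires bulging fontanelle or convulsions (convulsions being
# the sign that overlaps the residual other-infections picture); malaria
# requires fever. Remaining floors are reconstructions.
version: "reconstruction-1.0"
age_group: child
causes:
  - id: injury
    rule:
      {sign: injury_event, present: "yes"}
  - id: aids
    rule:
      {sign: wasting, present: "yes"}
  - id: malnutrition
    rule:
      any:
        - {sign: wasting, present: "yes"}
        - {sign: edema_feet, present: "yes"}
  - id: measles
    rule:
      all:
        - {sign: fever, present: "yes"}
        - {sign: rash, present: "yes"}
  - id: meningitis
    rule:
      any:
        - {sign: bulging_fontanelle, present: "yes"}
        - {sign: convulsions, present: "yes"}
  - id: dysentery
    rule:
      {sign: blood_in_stool, present: "yes"}
  - id: diarrhea
    rule:
      {sign: loose_stools, present: "yes"}
  - id: pertussis
    rule:
      {sign: cough, present: "yes"}
  - id: pneumonia
    rule:
      any:
        - {sign: difficult_breathing, present: "yes"}
        - {sign: fast_breathing, present: "yes"}
  - id: malaria
    rule:
      {sign: fever, present: "yes"}
  - id: hemorrhagic_fever
    rule:
      {sign: bleeding, present: "yes"}
  - id: other_infections
    rule:
      {sign: fever, present: "yes"}
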