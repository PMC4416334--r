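# Default expert-algorithm rule set for child deaths (1-59 months).
# Reconstructed criteria; see rules_neonate.yaml for the predicate grammar
# and the provenance note. The four "possible" tiers are deliberately more
# sensitive than their probable counterparts and are only eligible when the
# probable rule does not fire; possible malaria is fever with no other
# infectious diagnosis.
version: "reconstruction-1.0"
age_group: child
causes:
  - id: injury
    label: "Injury"
    tier: probable
    rule:
      {sign: injury_event, present: "yes"}
  - id: aids
    label: "AIDS"
    tier: probable
    rule:
      all:
        - {sign: wasting, present: "yes"}
        - any:
            - {sign: oral_thrush, present: "yes"}
            - {sign: swollen_glands, present: "yes"}
  - id: malnutrition
    label: "Malnutrition"
    tier: probable
    rule:
      any:
        - {sign: wasting, present: "yes"}
        - {sign: edema_feet, present: "yes"}
  - id: measles
    label: "Measles"
    tier: probable
    rule:
      all:
        - {sign: fever, present: "yes"}
        - {sign: rash, present: "yes"}
        - any:
            - {sign: cough, present: "yes"}
            - {sign: red_eyes, present: "yes"}
  - id: meningitis
    label: "Meningitis"
    tier: probable
    rule:
      all:
        - {sign: fever, present: "yes"}
        - any:
            - {sign: stiff_neck, present: "yes"}
            - {sign: bulging_fontanelle, present: "yes"}
  - id: dysentery
    label: "Dysentery"
    tier: probable
    rule:
      all:
        - {sign: loose_stools, present: "yes"}
        - {sign: blood_in_stool, present: "yes"}
  - id: diarrhea
    label: "Diarrhea"
    tier: probable
    rule:
      {sign: loose_stools, present: "yes", min_duration: 1}
  - id: pertussis
    label: "Pertussis"
    tier: probable
    rule:
      all:
        - {sign: cough, present: "yes", min_duration: 14}
        - any:
            - {sign: whooping_cough, present: "yes"}
            - {sign: post_tussive_vomiting, present: "yes"}
  - id: pneumonia
    label: "Pneumonia"
    tier: probable
    rule:
      all:
        - {sign: cough, present: "yes"}
        - any:
            - {sign: fast_breathing, present: "yes", min_duration: 2}
            - {sign: difficult_breathing, present: "yes", min_duration: 2}
  - id: malaria
    label: "Malaria"
    tier: probable
    rule:
      all:
        - {sign: fever, present: "yes"}
        - any:
            - {sign: convulsions, present: "yes"}
            - {sign: unconscious, present: "yes"}
  - id: hemorrhagic_fever
    label: "Hemorrhagic fever"
    tier: probable
    rule:
      all:
        - {sign: fever, present: "yes"}
        - {sign: bleeding, present: "yes"}
  - id: possible_dysentery
    label: "Possible dysentery"
    tier: possible
    counterpart: dysentery
    rule:
      {sign: blood_in_stool, present: "yes"}
  - id: possible_diarrhea
    label: "Possible diarrhea"
    tier: possible
    counterpart: diarrhea
    rule:
      {sign: loose_stools, present: "yes"}
  - id: possible_pneumonia
    label: "Possible pneumonia or ARI"
    tier: possible
    counterpart: pneumonia
    rule:
      all:
        - {sign: cough, present: "yes"}
        - any:
            - {sign: fast_breathing, present: "yes"}
            - {sign: difficult_breathing, present: "yes"}
  - id: possible_malaria
    label: "Possible malaria"
    tier: possible
    counterpart: malaria
    rule:
      all:
        - {sign: fever, present: "yes"}
        - not_cause:
            - aids
            - measles
            - meningitis
            - dysentery
            - diarrhea
            - pertussis
            - pneumonia
            - hemorrhagic_fever
            - possible_dysentery
            - possible_diarrhea
            - possible_pneumonia
  - id: other_infections
    label: "Other infections"
    tier: probable
    rule:
      {sign: fever, present: "yes"}
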