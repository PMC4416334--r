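# Default expert-algorithm rule set for neonatal deaths (0-27 days).
#
# The published algorithm compendium for this class of study is not fully
# reproduced in any single open text, so these criteria are RECONSTRUCTIONS:
# each rule keeps the anchored requirements that are documented (meningitis
# needing lethargy or unconsciousness on top of bulging fontanelle or stiff
# neck; minimum durations for respiratory signs; preterm delivery defined by
# pregnancy duration under 8 months, or under 9 months with respiratory
# distress) and fills the remainder with standard VA case definitions from
# the validation-study literature. Edit freely; the engine validates any
# rule set against the active vocabulary at load time.
#
# Predicate forms:
#   {sign: key, present: "yes"|"no", min_duration: d, max_duration: d}
#   {maternal_sign: key, present: "yes"|"no"}
#   {field: pregnancy_duration|illness_onset_day|age_at_death, lt|le|gt|ge: x}
#   {not_cause: [cause ids]}           # none of the named rules fires
# Combinators: all: [...], any: [...], not: {...}
version: "reconstruction-1.0"
age_group: neonate
causes:
  - id: neonatal_tetanus
    label: "Neonatal tetanus"
    tier: probable
    rule:
      all:
        - {sign: suckled_normally_first_2d, present: "yes"}
        - {sign: stopped_suckling, present: "yes"}
        - any:
            - {sign: convulsions, present: "yes"}
            - {sign: spasms, present: "yes"}
  - id: congenital_malformation
    label: "Congenital malformation"
    tier: probable
    rule:
      {sign: malformation, present: "yes"}
  - id: birth_injury_asphyxia
    label: "Birth injury and/or asphyxia"
    tier: probable
    rule:
      any:
        - {sign: not_breathe_at_birth, present: "yes"}
        - {sign: not_cry_at_birth, present: "yes"}
  - id: meningitis
    label: "Meningitis"
    tier: probable
    rule:
      all:
        - any:
            - {sign: bulging_fontanelle, present: "yes"}
            - {sign: stiff_neck, present: "yes"}
        - any:
            - {sign: lethargy, present: "yes"}
            - {sign: unconscious, present: "yes"}
  - id: diarrhea
    label: "Diarrhea"
    tier: probable
    rule:
      {sign: loose_stools, present: "yes", min_duration: 1}
  - id: pneumonia
    label: "Pneumonia"
    tier: probable
    rule:
      any:
        - {sign: fast_breathing, present: "yes", min_duration: 2}
        - all:
            - {sign: difficult_breathing, present: "yes", min_duration: 2}
            - {sign: chest_indrawing, present: "yes"}
  - id: sepsis
    label: "Sepsis"
    tier: probable
    rule:
      all:
        - any:
            - {sign: fever, present: "yes"}
            - {sign: hypothermia, present: "yes"}
        - any:
            - {sign: stopped_suckling, present: "yes"}
            - {sign: lethargy, present: "yes"}
            - {sign: unconscious, present: "yes"}
  - id: neonatal_jaundice
    label: "Neonatal jaundice"
    tier: probable
    rule:
      all:
        - {sign: yellow_skin, present: "yes"}
        - {sign: yellow_eyes, present: "yes"}
  - id: hemorrhagic_disease
    label: "Hemorrhagic disease of the newborn"
    tier: probable
    rule:
      {sign: bleeding, present: "yes"}
  - id: sudden_unexplained_death
    label: "Sudden unexplained death"
    tier: probable
    rule:
      {sign: died_suddenly, present: "yes"}
  - id: preterm_delivery
    label: "Preterm delivery"
    tier: probable
    rule:
      any:
        - {field: pregnancy_duration, lt: 8}
        - all:
            - {field: pregnancy_duration, lt: 9}
            - any:
                - {sign: grunting, present: "yes"}
                - {sign: chest_indrawing, present: "yes"}
maternal:
  # Maternal infection before or during labor and delivery (reconstruction).
  id: maternal_infection
  label: "Maternal infection before or during labor/delivery"
  rule:
    any:
      - {maternal_sign: m_fever_pregnancy, present: "yes"}
      - {maternal_sign: m_fever_labor, present: "yes"}
      - {maternal_sign: m_foul_discharge, present: "yes"}
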