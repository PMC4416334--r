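# Minimal diagnostic criteria the physician is required to verify before
# certifying each neonatal cause. Documented floors: meningitis requires at
# minimum bulging fontanelle or convulsions; pneumonia requires at least
# difficult or fast breathing (no duration floor, unlike the algorithm);
# preterm requires pregnancy duration under 8 months, or under 9 months
# with respiratory distress. The remaining floors are reconstructions.
version: "reconstruction-1.0"
age_group: neonate
causes:
  - id: neonatal_tetanus
    rule:
      any:
        - {sign: convulsions, present: "yes"}
        - {sign: spasms, present: "yes"}
  - id: congenital_malformation
    rule:
      {sign: malformation, present: "yes"}
  - id: birth_injury_asphyxia
    rule:
      any:
        - {sign: not_breathe_at_birth, present: "yes"}
        - {sign: not_cry_at_birth, present: "yes"}
  - id: meningitis
    rule:
      any:
        - {sign: bulging_fontanelle, present: "yes"}
        - {sign: convulsions, present: "yes"}
  - id: diarrhea
    rule:
      {sign: loose_stools, present: "yes"}
  - id: pneumonia
    rule:
      any:
        - {sign: difficult_breathing, present: "yes"}
        - {sign: fast_breathing, present: "yes"}
  - id: sepsis
    rule:
      any:
        - {sign: fever, present: "yes"}
        - {sign: hypothermia, present: "yes"}
  - id: neonatal_jaundice
    rule:
      {sign: yellow_skin, present: "yes"}
  - id: hemorrhagic_disease
    rule:
      {sign: bleeding, present: "yes"}
  - id: sudden_unexplained_death
    rule:
      {sign: died_suddenly, present: "yes"}
  - id: preterm_delivery
    rule:
      any:
        - {field: pregnancy_duration, lt: 8}
        - all:
            - {field: pregnancy_duration, lt: 9}
            - any:
                - {sign: grunting, present: "yes"}
                - {sign: chest_indrawing, present: "yes"}
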