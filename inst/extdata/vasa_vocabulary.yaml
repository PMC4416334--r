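# Sign/symptom vocabulary for the verbal autopsy record schema.
# The interview item list is configuration-defined: deployments blend a
# standard VA instrument with locally adapted wording, so the engine treats
# the vocabulary as data. Keys below are the defaults used by the shipped
# rule sets.
version: "default-1.0"
neonate:
  - fever
  - hypothermia
  - convulsions
  - spasms
  - bulging_fontanelle
  - stiff_neck
  - lethargy
  - unconscious
  - suckled_normally_first_2d
  - stopped_suckling
  - fast_breathing
  - difficult_breathing
  - chest_indrawing
  - grunting
  - loose_stools
  - blood_in_stool
  - vomiting
  - not_cry_at_birth
  - not_breathe_at_birth
  - malformation
  - yellow_skin
  - yellow_eyes
  - bleeding
  - died_suddenly
child:
  - fever
  - convulsions
  - unconscious
  - lethargy
  - stiff_neck
  - bulging_fontanelle
  - loose_stools
  - blood_in_stool
  - vomiting
  - cough
  - whooping_cough
  - post_tussive_vomiting
  - fast_breathing
  - difficult_breathing
  - chest_indrawing
  - rash
  - red_eyes
  - wasting
  - edema_feet
  - oral_thrush
  - swollen_glands
  - injury_event
  - bleeding
maternal:
  - m_fever_pregnancy
  - m_fever_labor
  - m_foul_discharge
  - m_prolonged_labor
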