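# Default neonatal cause hierarchy (rank 1 = top). Ordering principles:
# the most severe or site-specific infection outranks the less specific one
# (meningitis above sepsis), diarrhea sits above pneumonia, and preterm
# delivery is placed last so that it is selected as the primary cause only
# when it is the sole condition identified -- co-morbid conditions such as
# sepsis otherwise take precedence, mirroring ICD-10 practice for the main
# disease or condition of the infant.
# "comorbid" says whether the cause may be reported as a co-morbid
# diagnosis when it ranks below the primary.
age_group: neonate
order:
  - {cause: neonatal_tetanus, comorbid: false}
  - {cause: congenital_malformation, comorbid: false}
  - {cause: birth_injury_asphyxia, comorbid: true}
  - {cause: meningitis, comorbid: true}
  - {cause: diarrhea, comorbid: true}
  - {cause: pneumonia, comorbid: true}
  - {cause: sepsis, comorbid: true}
  - {cause: neonatal_jaundice, comorbid: false}
  - {cause: hemorrhagic_disease, comorbid: true}
  - {cause: sudden_unexplained_death, comorbid: false}
  - {cause: preterm_delivery, comorbid: true}
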