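# Event-group term resource. Licensed MedDRA SMQ membership cannot be
# redistributed; these editable lists are seeded with every preferred term
# printed in the published group tables, each under its published group, plus
# a few canonical members for generator realism. `placeholder_prefixes`
# recognise the synthetic placeholder terms that stand in for the unprinted
# appendix detail (labelled "(synthetic N)").
version: approximate-terms-1.0
scope: unstated-in-source   # narrow vs broad SMQ scope is not recorded
groups:
  termination_abortion:
    terms:
      - Abortion spontaneous
      - Abortion
      - Abortion missed
      - Abortion induced
      - Abortion threatened
      - Foetal death
      - Stillbirth
    placeholder_prefixes:
      - abortion related event (synthetic
  pregnancy_labour_delivery:
    terms:
      - Caesarean section
      - Premature delivery
      - Gestational diabetes
      - Pre-eclampsia
      - Premature labour
      - Premature rupture of membranes
      - Premature separation of placenta
      - Placenta praevia
      - Ectopic pregnancy
    placeholder_prefixes:
      - premature labour related event (synthetic
  neonatal_disorders:
    terms:
      - Premature baby
      - Low birth weight baby
      - Anaemia neonatal
      - Jaundice neonatal
      - Respiratory distress of newborn
    placeholder_prefixes:
      - neonatal disorder (synthetic
  congenital_familial_genetic:
    terms:
      - Trisomy 21
      - Atrial septal defect
      - Ventricular septal defect
      - Talipes
      - Congenital anomaly
      - Cleft lip
    placeholder_prefixes:
      - congenital anomaly (synthetic
  foetal_disorders:
    terms:
      - Foetal growth restriction
      - Foetal heart rate abnormal
      - Foetal malformation
      - Foetal distress syndrome
      - Foetal hypokinesia
    placeholder_prefixes:
      - foetal disorder (synthetic
# Terms that do not indicate an ADR: exposure coding of the special condition
# and conditions merely predisposing to an ADR.
not_indicating_adr:
  terms:
    - Maternal exposure during pregnancy
    - Foetal exposure during pregnancy
    - Exposure during pregnancy
    - Exposure in utero
    - Drug exposure during pregnancy
    - Maternal exposure before pregnancy
    - Drug exposure before pregnancy
    - Exposure via breast milk
    - Drug exposure via breast milk
    - Maternal exposure during breast feeding
    - Exposure during breastfeeding
    - Maternal exposure timing unspecified
    - Foetal exposure timing unspecified
  placeholder_prefixes:
    - predisposing condition (synthetic
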