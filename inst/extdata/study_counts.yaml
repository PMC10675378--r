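# Published marginal tables of the EudraVigilance pregnancy/lactation DMT
# case set (1 Jan 2019 - 31 Dec 2022 download window). Counts are per drug in
# the order given by `drug_order`. These numbers parameterise the exact-count
# case set and the stochastic generator defaults.
drug_order: [glatiramer, alemtuzumab, natalizumab, ocrelizumab]
cases: [201, 100, 839, 96]
events: [720, 666, 1943, 261]
table1:
  child_age:
    foetus: [2, 3, 5, 5]
    neonate_0_1m: [13, 8, 107, 7]
    infant_2m_2y: [6, 4, 25, 3]
  mother_age:
    "12_17": [1, 0, 2, 0]
    "18_64": [126, 72, 481, 40]
  age_not_specified: [53, 13, 219, 41]
  baby_sex:
    female: [6, 8, 35, 4]
    male: [12, 4, 45, 8]
    not_specified: [3, 3, 57, 3]
  reporter:
    healthcare_professional: [117, 84, 766, 84]
    non_healthcare_professional: [84, 16, 73, 12]
  region:
    EEA: [145, 67, 529, 41]
    non_EEA: [56, 33, 310, 55]
  seriousness:
    not_serious: [36, 31, 168, 15]
    serious: [165, 69, 671, 81]
  exposure:
    during_pregnancy_or_transplacental: [180, 39, 770, 59]
    breastfeeding_or_transmammary: [6, 3, 22, 3]
    before_pregnancy: [4, 22, 0, 20]
    timing_unspecified: [0, 4, 2, 7]
    not_specified: [11, 32, 45, 7]
  suspect_other:
    "0": [150, 85, 604, 82]
    "1": [28, 6, 178, 8]
    "2": [16, 4, 46, 6]
    "3": [1, 3, 6, 0]
    "4_plus": [6, 2, 5, 0]
  concomitant:
    "1": [10, 7, 49, 5]
    "2": [8, 3, 36, 11]
    "3": [4, 4, 21, 1]
    "4": [1, 4, 12, 3]
    "5_plus": [4, 10, 24, 6]
    not_reported: [174, 72, 697, 70]
# Event counts by group; `pts` lists the four most-reported preferred terms
# per group (full per-term appendix detail is not public; the remainder of
# each group total is represented by synthetic placeholder terms).
table2:
  maternal_other:
    total: [254, 501, 204, 69]
    pts:
      "Multiple sclerosis relapse": [30, 5, 28, 5]
      "Haemorrhage": [2, 2, 8, 3]
      "Anaemia": [4, 2, 7, 0]
      "Dyspnoea": [4, 7, 1, 1]
  termination_abortion:
    total: [55, 20, 266, 38]
    pts:
      "Abortion spontaneous": [42, 13, 235, 31]
      "Abortion": [6, 2, 8, 0]
      "Abortion missed": [3, 0, 6, 3]
      "Foetal death": [1, 1, 2, 2]
  pregnancy_labour_delivery:
    total: [54, 7, 284, 15]
    pts:
      "Caesarean section": [13, 0, 93, 0]
      "Premature delivery": [2, 0, 35, 3]
      "Gestational diabetes": [6, 1, 8, 3]
      "Pre-eclampsia": [1, 0, 16, 0]
  neonatal_disorders:
    total: [18, 8, 130, 6]
    pts:
      "Premature baby": [5, 1, 52, 4]
      "Low birth weight baby": [1, 0, 24, 0]
      "Anaemia neonatal": [0, 0, 16, 1]
      "Jaundice neonatal": [1, 0, 5, 0]
  congenital_familial_genetic:
    total: [23, 8, 103, 5]
    pts:
      "Trisomy 21": [0, 0, 6, 1]
      "Atrial septal defect": [2, 1, 3, 0]
      "Ventricular septal defect": [1, 0, 4, 0]
      "Talipes": [0, 0, 4, 0]
  neonatal_other:
    total: [3, 18, 56, 12]
    pts:
      "Thrombocytopaenia": [0, 0, 9, 0]
      "Anaemia": [0, 0, 4, 0]
      "Platelet count decreased": [0, 0, 3, 0]
      "Anti-thyroid antibody positive": [0, 2, 0, 0]
  foetal_disorders:
    total: [12, 4, 36, 1]
    pts:
      "Foetal growth restriction": [5, 3, 10, 1]
      "Foetal heart rate abnormal": [2, 0, 5, 0]
      "Foetal malformation": [2, 0, 5, 0]
      "Foetal distress syndrome": [0, 0, 4, 0]
  infant_other:
    total: [9, 5, 20, 10]
    pts:
      "Anaemia": [0, 0, 3, 0]
      "Autism spectrum disorder": [0, 0, 3, 0]
      "COVID-19": [2, 0, 0, 1]
      "Blood thyroid-stimulating hormone decreased": [0, 2, 0, 0]
  foetal_other:
    total: [0, 6, 0, 4]
    pts:
      "Bladder dilatation": [0, 0, 0, 1]
      "Cerebral calcification": [0, 1, 0, 0]
      "Cerebral cyst": [0, 1, 0, 0]
      "Cerebral ventricle dilatation": [0, 1, 0, 0]
table3:
  seriousness:
    death: [2, 1, 67, 8]
    life_threatening: [1, 3, 10, 0]
    hospitalisation: [141, 99, 334, 27]
    disabling: [4, 0, 0, 0]
    congenital_anomaly: [22, 3, 171, 7]
    other_medically_important: [341, 330, 978, 89]
    none: [209, 230, 383, 130]
  outcome:
    recovered_resolved: [108, 64, 1117, 37]
    recovering_resolving: [14, 21, 9, 0]
    recovered_with_sequelae: [9, 0, 11, 2]
    not_recovered: [45, 231, 109, 11]
    fatal: [2, 1, 67, 8]
    unknown: [542, 349, 630, 203]
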