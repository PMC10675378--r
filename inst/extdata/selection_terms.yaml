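# Case-selection vocabulary for pregnancy/lactation reports. All matching is
# case-insensitive on whitespace-normalised text; the exact list is checked
# before the substring word list. Editable: the shipped word list is exactly
# the published retrieval list (possibly non-exhaustive by design).
inclusion_pt_exact:
  - maternal exposure during pregnancy
  - foetal exposure during pregnancy
  - exposure during pregnancy
  - exposure in utero
  - drug exposure during pregnancy
  - maternal exposure before pregnancy
  - drug exposure before pregnancy
  - exposure via breast milk
  - drug exposure via breast milk
  - maternal exposure during breast feeding
  - exposure during breastfeeding
  - maternal exposure timing unspecified
  - foetal exposure timing unspecified
inclusion_pt_substrings:
  - foetal
  - placental
  - premature
  - milk
  - breastfeeding
  - maternal
  - neonatal
  - baby
  - abortion
  - still birth
  - malformation
  - congenital
  - foetal death
inclusion_route_terms:
  - transplacental
  - transmammary
  - maternal exposure timing unspecified
# Exclusions. Paternal-exposure reports are excluded outright. The
# adult-age-conflict list names adult conditions that the word search pulls
# in ("premature", etc. used of the adult patient); it fires only when the
# case has no other pregnancy/lactation evidence.
exclusion_paternal_substrings:
  - paternal
exclusion_adult_conflict_terms:
  - premature menopause
  - premature ovarian failure
  - premature ejaculation
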