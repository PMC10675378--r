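# Canonical line-listing dialect: UTF-8 CSV, one row per case, reactions
# packed into one cell as "PT (duration – outcome – criterion; criterion)"
# with ", " between events. The long dialect unpacks to one row per event.
name: canonical
columns:
  case_id: "EU Local Number"
  drug_group: "Drug Group"
  report_type: "Report Type"
  reporter: "Primary Source Qualification"
  region: "Primary Source Country for Regulatory Purposes"
  mother_age_group: "Patient Age Group"
  child_age_group: "Child Age Group"
  baby_sex: "Baby Sex"
  suspect_drugs: "Suspect/Interacting Drug List"
  concomitant_drugs: "Concomitant Drug List"
  reactions: "Reaction List PT"
long_columns:
  event_index: "Event Index"
  pt: "Reaction PT"
  duration: "Duration"
  outcome: "Outcome"
  seriousness: "Seriousness Criteria"
  subject: "Subject"
separators:
  event: ", "
  field: " – "
  criteria: "; "
  drug: "; "
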