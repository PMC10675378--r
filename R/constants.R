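#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used throughout the package. Values are stored as
## lower_snake tokens; display strings (as they appear in public line-listing
## exports) live in the dialect maps in R/dialect.R.

#' Drugs of interest
#'
#' The four disease-modifying therapies analysed: glatiramer (the comparator)
#' and the three monoclonal antibodies.
#'
#' @return Character vector of drug tokens.
#' @export
dmt_drugs <- function() {
  c("glatiramer", "alemtuzumab", "natalizumab", "ocrelizumab")
}

outcome_levels <- function() {
  c("recovered_resolved", "recovering_resolving", "recovered_with_sequelae",
    "not_recovered", "fatal", "unknown")
}

seriousness_levels <- function() {
  c("death", "life_threatening", "hospitalisation", "disabling",
    "congenital_anomaly", "other_medically_important", "none")
}

subject_levels <- function() {
  c("mother", "foetus", "neonate", "infant", "unspecified")
}

report_type_levels <- function() c("spontaneous", "not_spontaneous")

reporter_levels <- function() {
  c("healthcare_professional", "non_healthcare_professional")
}

region_levels <- function() c("EEA", "non_EEA")

mother_age_levels <- function() c("12_17", "18_64", "65_plus", "not_specified")

child_age_levels <- function() c("foetus", "neonate_0_1m", "infant_2m_2y", "none")

baby_sex_levels <- function() c("female", "male", "not_specified")

drug_role_levels <- function() c("suspect", "interacting", "concomitant")

#' Event groups
#'
#' The ten mutually exclusive groups every reaction term is assigned to:
#' the five pregnancy-and-neonatal SMQ subtopics, four subject-specific
#' "other ADR" groups, and the terms that do not indicate an ADR (exposure
#' coding and predisposing conditions).
#'
#' @return Character vector of the ten group tokens, SMQ groups first.
#' @export
event_groups <- function() {
  c("termination_abortion", "pregnancy_labour_delivery", "neonatal_disorders",
    "congenital_familial_genetic", "foetal_disorders",
    "foetal_other", "neonatal_other", "infant_other", "maternal_other",
    "not_indicating_adr")
}

smq_group_names <- function() event_groups()[1:5]

adr_group_names <- function() event_groups()[1:9]

exposure_class_levels <- function() {
  c("during_pregnancy_or_transplacental", "breastfeeding_or_transmammary",
    "before_pregnancy", "timing_unspecified", "not_specified")
}
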