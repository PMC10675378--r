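## Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

exact_fixture <- function() cached("fixture", fixture_exact_counts())

exact_selected <- function() {
  cached("selected", select_cases(exact_fixture()$cases))
}

exact_assignments <- function() {
  cached("assignments", assign_groups(exact_selected()$selected))
}

exact_group_counts <- function() {
  cached("group_counts", group_counts(exact_assignments()))
}

## A small hand-built collection: one helper to cut fixture boilerplate in
## unit tests. `events` is a list (one element per case) of data frames with
## pt and optional outcome/seriousness; drugs defaults to a single suspect
## mention of the drug of interest.
mini_set <- function(drug_group, events, child_age = "none",
                     mother_age = "18_64", route = "") {
  n <- length(events)
  ids <- sprintf("C%03d", seq_len(n))
  child_age <- rep_len(child_age, n)
  route <- rep_len(route, n)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- as.data.frame(events[[i]], stringsAsFactors = FALSE)
    if (is.null(e$outcome)) e$outcome <- "unknown"
    if (is.null(e$seriousness)) e$seriousness <- "other_medically_important"
    data.frame(drug_group = drug_group, case_id = ids[i],
               event_index = seq_len(nrow(e)), pt = e$pt, duration = "",
               outcome = e$outcome, seriousness = e$seriousness,
               subject = "unspecified", stringsAsFactors = FALSE)
  }))
  icsr_set(
    cases = data.frame(drug_group = drug_group, case_id = ids,
                       report_type = "spontaneous",
                       reporter = "healthcare_professional", region = "EEA",
                       mother_age_group = rep_len(mother_age, n),
                       child_age_group = child_age,
                       baby_sex = NA_character_, stringsAsFactors = FALSE),
    drugs = data.frame(drug_group = drug_group, case_id = ids,
                       name = drug_group, role = "suspect", route = route,
                       stringsAsFactors = FALSE),
    events = ev)
}

## Random 2x2 tables with strictly positive cells.
random_tables <- function(n, seed, max_cell = 2000) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell, n, replace = TRUE))
}

published_drug_order <- function() study_counts()$drug_order
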