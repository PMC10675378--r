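#' Individual case safety report collection
#'
#' An `icsr_set` holds a collection of individual case safety reports (ICSRs)
#' in relational form: one row per case in `cases`, one row per drug mention
#' in `drugs`, one row per reaction event in `events`. A case is identified by
#' the pair (`drug_group`, `case_id`): case ids are unique within the export
#' of one drug of interest but the same id may legitimately recur across drug
#' exports, because the analysis is per drug.
#'
#' @param cases Data frame with columns `drug_group`, `case_id`,
#'   `report_type`, `reporter`, `region`, `mother_age_group`,
#'   `child_age_group`, `baby_sex` (NA when no child is involved).
#' @param drugs Data frame with columns `drug_group`, `case_id`, `name`,
#'   `role` (suspect/interacting/concomitant), `route` ("" when unreported).
#' @param events Data frame with columns `drug_group`, `case_id`,
#'   `event_index`, `pt`, `duration`, `outcome`, `seriousness` (";"-joined
#'   criterion tokens), `subject`.
#' @param validate Check the invariants on construction (default TRUE).
#' @return An object of class `icsr_set`.
#' @export
icsr_set <- function(cases, drugs, events, validate = TRUE) {
  x <- structure(list(cases = as.data.frame(cases, stringsAsFactors = FALSE),
                      drugs = as.data.frame(drugs, stringsAsFactors = FALSE),
                      events = as.data.frame(events, stringsAsFactors = FALSE)),
                 class = "icsr_set")
  rownames(x$cases) <- NULL
  rownames(x$drugs) <- NULL
  rownames(x$events) <- NULL
  if (validate) validate_icsr_set(x)
  x
}

case_cols <- function() {
  c("drug_group", "case_id", "report_type", "reporter", "region",
    "mother_age_group", "child_age_group", "baby_sex")
}

drug_cols <- function() c("drug_group", "case_id", "name", "role", "route")

event_cols <- function() {
  c("drug_group", "case_id", "event_index", "pt", "duration", "outcome",
    "seriousness", "subject")
}

case_key <- function(df) paste(df$drug_group, df$case_id, sep = "\r")

#' Validate an ICSR collection
#'
#' Checks the structural invariants: unique case ids within each drug export,
#' at least one event per case, at least one suspect mention matching the
#' export's drug of interest, non-empty preferred terms, and valid
#' vocabulary values. A fatal outcome without a results-in-death seriousness
#' criterion is reported as a consistency warning, not an error (real exports
#' contain such records).
#'
#' @param x An `icsr_set`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_icsr_set <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  for (part in c("cases", "drugs", "events")) {
    need <- switch(part, cases = case_cols(), drugs = drug_cols(),
                   events = event_cols())
    miss <- setdiff(need, names(x[[part]]))
    if (length(miss) > 0) {
      stop(sprintf("icsr_set$%s is missing column(s): %s", part,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  cs <- x$cases
  if (nrow(cs) == 0) {
    if (nrow(x$events) > 0 || nrow(x$drugs) > 0) {
      stop("events/drugs present for an empty case table", call. = FALSE)
    }
    return(invisible(x))
  }
  dup <- cs[duplicated(case_key(cs)), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate case id(s) within a drug export: %s",
                 paste(unique(paste0(dup$drug_group, ":", dup$case_id)),
                       collapse = ", ")), call. = FALSE)
  }
  assert_in(cs$report_type, report_type_levels(), "report_type")
  assert_in(cs$reporter, reporter_levels(), "reporter")
  assert_in(cs$region, region_levels(), "region")
  assert_in(cs$mother_age_group, c(mother_age_levels(), NA), "mother_age_group")
  assert_in(cs$child_age_group, child_age_levels(), "child_age_group")
  assert_in(cs$baby_sex[!is.na(cs$baby_sex)], baby_sex_levels(), "baby_sex")
  ev <- x$events
  if (any(!nzchar(norm_ws(ev$pt)))) {
    stop("empty preferred term in events", call. = FALSE)
  }
  assert_in(ev$outcome, outcome_levels(), "outcome")
  assert_in(ev$subject, subject_levels(), "subject")
  crit <- unlist(split_criteria(ev$seriousness))
  assert_in(crit, seriousness_levels(), "seriousness criterion")
  mixed <- vapply(split_criteria(ev$seriousness),
                  function(s) "none" %in% s && length(s) > 1, logical(1))
  if (any(mixed)) {
    stop("seriousness 'none' cannot be combined with a serious criterion",
         call. = FALSE)
  }
  no_events <- setdiff(case_key(cs), case_key(ev))
  if (length(no_events) > 0) {
    stop(sprintf("%d case(s) have no reaction events", length(no_events)),
         call. = FALSE)
  }
  sus <- x$drugs[x$drugs$role == "suspect", , drop = FALSE]
  sus_ok <- norm_term(sus$name) == norm_term(sus$drug_group)
  covered <- unique(case_key(sus[sus_ok, , drop = FALSE]))
  if (length(setdiff(case_key(cs), covered)) > 0) {
    stop("every case needs a suspect mention of its export's drug of interest",
         call. = FALSE)
  }
  assert_in(x$drugs$role, drug_role_levels(), "drug role")
  fatal_bad <- ev$outcome == "fatal" &
    !vapply(split_criteria(ev$seriousness), function(s) "death" %in% s,
            logical(1))
  if (any(fatal_bad)) {
    warning(sprintf(
      "%d fatal event(s) lack the results-in-death seriousness criterion",
      sum(fatal_bad)), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.icsr_set <- function(x, ...) {
  by_drug <- table(x$cases$drug_group)
  cat(sprintf("<icsr_set> %d cases, %d events, %d drug mentions\n",
              nrow(x$cases), nrow(x$events), nrow(x$drugs)))
  if (nrow(x$cases) > 0) {
    cat("  cases by drug of interest:",
        paste(sprintf("%s=%d", names(by_drug), as.integer(by_drug)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cases / events in a collection
#' @param x An `icsr_set`.
#' @return Integer count.
#' @export
n_cases <- function(x) nrow(x$cases)

#' @rdname n_cases
#' @export
n_events <- function(x) nrow(x$events)

## Case-level seriousness: a case is serious iff any of its events carries a
## serious criterion. Returns a logical vector aligned with x$cases.
case_serious <- function(x) {
  ev_serious <- is_serious_event(x$events$seriousness)
  agg <- tapply(ev_serious, case_key(x$events), any)
  as.logical(agg[case_key(x$cases)])
}

## Subset a collection to the cases whose (drug_group, case_id) key is in
## `keys`; keeps relational consistency.
subset_cases <- function(x, keys) {
  icsr_set(x$cases[case_key(x$cases) %in% keys, , drop = FALSE],
           x$drugs[case_key(x$drugs) %in% keys, , drop = FALSE],
           x$events[case_key(x$events) %in% keys, , drop = FALSE],
           validate = FALSE)
}

## Concatenate icsr_set objects (no key checks; callers validate).
bind_icsr_sets <- function(sets) {
  icsr_set(do.call(rbind, lapply(sets, `[[`, "cases")),
           do.call(rbind, lapply(sets, `[[`, "drugs")),
           do.call(rbind, lapply(sets, `[[`, "events")),
           validate = FALSE)
}
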