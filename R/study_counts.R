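#' Published marginal tables of the study case set
#'
#' The per-drug case and event totals, the case-characteristics table, the
#' event-group/preferred-term table (four most-reported terms per group) and
#' the seriousness/outcome table, as printed for the 2019-2022 download.
#' These counts are the inputs that parameterise the exact-count case set
#' ([fixture_exact_counts()]) and the generator defaults
#' ([default_config()]).
#'
#' @return Nested list mirroring the packaged `study_counts.yaml`, with
#'   `drug_order`, `cases`, `events`, `table1`, `table2`, `table3`.
#' @export
study_counts <- function() {
  sc <- read_resource("study_counts.yaml")
  stopifnot(setequal(sc$drug_order, dmt_drugs()))
  sc
}

## Placeholder preferred-term labels per group for the unprinted remainder
## of each group total. Placeholders carry a wording cue that makes their
## group recoverable (SMQ prefix match, or a subject word for the
## subject-defined groups) and are numbered per drug so that no synthetic
## term accumulates counts across drugs.
group_placeholder_label <- function() {
  c(termination_abortion = "Abortion related event",
    pregnancy_labour_delivery = "Premature labour related event",
    neonatal_disorders = "Neonatal disorder",
    congenital_familial_genetic = "Congenital anomaly",
    foetal_disorders = "Foetal disorder",
    maternal_other = "Unspecified maternal event",
    neonatal_other = "Unspecified neonatal event",
    infant_other = "Unspecified infant event",
    foetal_other = "Unspecified foetal event")
}

placeholder_pt <- function(group, drug, j) {
  sprintf("%s (synthetic %s %d)", group_placeholder_label()[[group]], drug, j)
}

## Per-drug pool of ADR events implied by the group table: printed terms at
## their printed counts, remainder as numbered placeholders. Returns a data
## frame (pt, group) with one row per event.
drug_event_pool <- function(sc, di) {
  drug <- sc$drug_order[di]
  rows <- lapply(names(sc$table2), function(g) {
    spec <- sc$table2[[g]]
    pts <- names(spec$pts)
    n_pt <- vapply(spec$pts, `[[`, numeric(1), di)
    pt_rep <- rep(pts, n_pt)
    printed <- data.frame(pt = pt_rep, group = rep(g, length(pt_rep)),
                          stringsAsFactors = FALSE)
    rem <- spec$total[di] - sum(n_pt)
    stopifnot(rem >= 0)
    ph <- if (rem > 0) {
      data.frame(pt = vapply(seq_len(rem),
                             function(j) placeholder_pt(g, drug, j),
                             character(1)),
                 group = rep(g, rem), stringsAsFactors = FALSE)
    }
    rbind(printed, ph)
  })
  do.call(rbind, rows)
}
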