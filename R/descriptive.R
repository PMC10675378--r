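## Builders for the three descriptive outputs: case characteristics,
## seriousness/outcome distribution, and summary scalars. Percentages are
## always recomputed from counts, half-up to 1 decimal; case-level blocks
## use the per-drug case totals as denominator, event-level blocks the
## per-drug event totals.

count_block <- function(values, levels, drug, drugs, denom) {
  f <- table(factor(values, levels = levels),
             factor(drug, levels = drugs))
  out <- data.frame(level = levels, as.data.frame.matrix(f),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$total <- rowSums(f)
  for (d in drugs) out[[paste0(d, "_pct")]] <- pct(out[[d]], denom[[d]])
  out$total_pct <- pct(out$total, sum(unlist(denom)))
  rownames(out) <- NULL
  out
}

#' Case characteristics table
#'
#' Per-drug and total counts (with percentages of the per-drug case total)
#' for: age (child age groups, mother age groups, not specified), baby sex
#' (over cases involving a child), type of reporting, primary source
#' qualification, geographic region, case seriousness, exposure type, and
#' the number of suspect drugs other than the drug of interest and of
#' concomitant drugs.
#'
#' @param x A selected `icsr_set` with an `exposure_class` column (from
#'   [select_cases()]).
#' @return Data frame with columns `block`, `level`, one count column per
#'   drug, `total`, and matching `_pct` columns.
#' @export
tabulate_characteristics <- function(x) {
  stopifnot(inherits(x, "icsr_set"),
            "exposure_class" %in% names(x$cases))
  cs <- x$cases
  drugs <- intersect(dmt_drugs(), unique(cs$drug_group))
  if (length(drugs) == 0) drugs <- unique(cs$drug_group)
  denom <- as.list(table(factor(cs$drug_group, levels = drugs)))
  blk <- function(name, values, levels, subset = NULL) {
    v <- if (is.null(subset)) values else values[subset]
    d <- if (is.null(subset)) cs$drug_group else cs$drug_group[subset]
    cbind(block = name, count_block(v, levels, d, drugs, denom))
  }
  child <- cs$child_age_group != "none"
  age_level <- ifelse(child, cs$child_age_group,
                      ifelse(is.na(cs$mother_age_group), "not_specified",
                             cs$mother_age_group))
  n_other_suspect <- count_drug_strata(x, "suspect")
  n_concomitant <- count_drug_strata(x, "concomitant")
  serious <- ifelse(case_serious(x), "serious", "not_serious")
  rbind(
    blk("age", age_level,
        c("foetus", "neonate_0_1m", "infant_2m_2y", "12_17", "18_64",
          "65_plus", "not_specified")),
    blk("baby_sex",
        ifelse(is.na(cs$baby_sex), "not_specified", cs$baby_sex),
        baby_sex_levels(), subset = child),
    blk("report_type", cs$report_type, report_type_levels()),
    blk("reporter", cs$reporter, reporter_levels()),
    blk("region", cs$region, region_levels()),
    blk("seriousness", serious, c("not_serious", "serious")),
    blk("exposure", cs$exposure_class, exposure_class_levels()),
    blk("suspect_other", n_other_suspect,
        c("0", "1", "2", "3", "4_plus")),
    blk("concomitant", n_concomitant,
        c("1", "2", "3", "4", "5_plus", "not_reported")))
}

## Stratum label for the number of suspect mentions other than the drug of
## interest, or of concomitant mentions.
count_drug_strata <- function(x, which = c("suspect", "concomitant")) {
  which <- match.arg(which)
  dr <- x$drugs
  if (which == "suspect") {
    sel <- dr$role != "concomitant" &
      norm_term(dr$name) != norm_term(dr$drug_group)
  } else {
    sel <- dr$role == "concomitant"
  }
  n <- table(factor(case_key(dr)[sel], levels = case_key(x$cases)))
  n <- as.integer(n)
  if (which == "suspect") {
    ifelse(n >= 4, "4_plus", as.character(n))
  } else {
    ifelse(n == 0, "not_reported", ifelse(n >= 5, "5_plus", as.character(n)))
  }
}

#' Seriousness and outcome distribution of events
#'
#' Per-drug event counts (with percentages of the per-drug event totals)
#' for the six seriousness criteria plus not-serious, and for the six
#' outcomes. An event carrying several criteria counts once under each; the
#' outcome block sums exactly to the per-drug event totals.
#'
#' @param x An `icsr_set`.
#' @return Data frame with columns `block`, `level`, per-drug counts,
#'   `total`, and `_pct` columns.
#' @export
tabulate_seriousness_outcome <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  ev <- x$events
  drugs <- intersect(dmt_drugs(), unique(ev$drug_group))
  if (length(drugs) == 0) drugs <- unique(ev$drug_group)
  denom <- as.list(table(factor(ev$drug_group, levels = drugs)))
  crit <- split_criteria(ev$seriousness)
  crit_long <- data.frame(
    drug_group = rep(ev$drug_group, lengths(crit)),
    level = unlist(crit), stringsAsFactors = FALSE)
  crit_tab <- count_block(crit_long$level, seriousness_levels(),
                          crit_long$drug_group, drugs, denom)
  out_tab <- count_block(ev$outcome, outcome_levels(), ev$drug_group,
                         drugs, denom)
  rbind(cbind(block = "seriousness", crit_tab),
        cbind(block = "outcome", out_tab))
}

#' Mean number of events per case
#'
#' @param x A non-empty `icsr_set`.
#' @param digits Decimals of the reported value (1, as published).
#' @return Total events divided by total cases, half-up rounded.
#' @export
mean_events_per_case <- function(x, digits = 1) {
  stopifnot(inherits(x, "icsr_set"))
  if (n_cases(x) == 0) stop("undefined for an empty case set", call. = FALSE)
  round_half_up(n_events(x) / n_cases(x), digits)
}

#' Most-reported preferred terms per event group
#'
#' Ranks preferred terms within each group by their total count over all
#' drugs; ties broken by alphabetical order of the term.
#'
#' @param counts Output of [group_counts()].
#' @param k Number of terms per group (published tables use 4).
#' @return Data frame `group`, `rank`, `pt`, `total` (k rows per non-empty
#'   group; empty when `k = 0`).
#' @export
top_pts_per_group <- function(counts, k = 4) {
  pts <- counts$pts
  out <- lapply(split(pts, factor(pts$group, levels = event_groups())),
                function(g) {
    if (nrow(g) == 0 || k == 0) return(NULL)
    g <- g[order(-g$total, g$pt), , drop = FALSE]
    g <- utils::head(g, k)
    data.frame(group = g$group, rank = seq_len(nrow(g)), pt = g$pt,
               total = g$total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(group = character(), rank = integer(),
                      pt = character(), total = integer())
  }
  rownames(out) <- NULL
  out
}
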