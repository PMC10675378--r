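#' Build a 2x2 reporting contingency table
#'
#' For a target event (a group or a preferred term), the drug of interest
#' and the comparator: `a` = target events reported with the drug, `b` = its
#' other events, `c` = target events with the comparator, `d` = its other
#' events. The per-drug totals include the events not indicating an ADR
#' (this denominator convention reproduces the published estimates).
#'
#' @param counts Data frame of target event counts with a column naming the
#'   target (`group` or `pt`) and one count column per drug.
#' @param target Target value to look up.
#' @param drug,comparator Drug tokens; must differ.
#' @param totals Named integer vector of total events per drug. Defaults to
#'   the column sums of `counts`, which is only correct when `counts` is a
#'   full partition (such as the ten-group table).
#' @return List of class `contingency_2x2` with integer `a`, `b`, `c`, `d`
#'   and the labels.
#' @export
build_contingency <- function(counts, target, drug, comparator,
                              totals = NULL) {
  stopifnot(drug != comparator)
  target_col <- intersect(c("pt", "target", "group"), names(counts))[1]
  if (is.na(target_col)) stop("counts needs a target column", call. = FALSE)
  for (d in c(drug, comparator)) {
    if (!d %in% names(counts)) {
      stop("unknown drug in counts table: ", d, call. = FALSE)
    }
  }
  rows <- counts[counts[[target_col]] == target, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown target: ", target, call. = FALSE)
  if (is.null(totals)) {
    totals <- vapply(c(drug, comparator), function(d) sum(counts[[d]]),
                     numeric(1))
  }
  a <- sum(rows[[drug]])
  c_ <- sum(rows[[comparator]])
  structure(list(target = target, drug = drug, comparator = comparator,
                 a = as.integer(a),
                 b = as.integer(totals[[drug]] - a),
                 c = as.integer(c_),
                 d = as.integer(totals[[comparator]] - c_)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<2x2> %s: %s vs %s  a=%d b=%d c=%d d=%d\n", x$target,
              x$drug, x$comparator, x$a, x$b, x$c, x$d))
  invisible(x)
}

tbl_counts <- function(t) {
  if (inherits(t, "contingency_2x2") || is.list(t)) {
    c(a = t$a, b = t$b, c = t$c, d = t$d)
  } else {
    stats::setNames(as.numeric(t[1:4]), c("a", "b", "c", "d"))
  }
}

#' Reporting odds ratio
#'
#' ROR = (a/c)/(b/d) = ad/(bc). Undefined (NA) when any cell is zero: no
#' continuity correction is applied; zero-cell results are flagged as not
#' estimable rather than shifted.
#'
#' @param t A `contingency_2x2` (or list/vector with a, b, c, d).
#' @return Unrounded positive ROR, or NA when not estimable.
#' @export
compute_ror <- function(t) {
  n <- tbl_counts(t)
  if (any(n < 0) || any(n != floor(n))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(n == 0)) return(NA_real_)
  unname((n["a"] / n["c"]) / (n["b"] / n["d"]))
}

#' Woolf confidence interval for the ROR
#'
#' Log-normal interval exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' This is the interval that reproduces the published bounds.
#'
#' @param t A `contingency_2x2` (or list/vector with a, b, c, d).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Named vector `c(low, high)`, NA when any cell is zero.
#' @export
woolf_ci <- function(t, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  n <- tbl_counts(t)
  if (any(n == 0)) return(c(low = NA_real_, high = NA_real_))
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(sum(1 / n))
  lr <- log(compute_ror(t))
  c(low = exp(lr - z * se), high = exp(lr + z * se))
}

#' Preferred terms eligible for term-level disproportionality
#'
#' The published rule: a term qualifies only when it is reported in at
#' least `min_cases` cases for each drug. Counts are distinct reporting
#' cases (not events), and terms not indicating an ADR are not candidates.
#'
#' @param assignments Output of [assign_groups()].
#' @param drugs Drugs that must each reach the threshold (default the four
#'   DMTs).
#' @param min_cases Threshold (default 3).
#' @return Character vector of eligible preferred terms (alphabetical).
#' @export
eligible_pts <- function(assignments, drugs = dmt_drugs(), min_cases = 3) {
  adr <- assignments[assignments$group != "not_indicating_adr", , drop = FALSE]
  if (nrow(adr) == 0) return(character())
  one <- unique(adr[, c("drug_group", "case_id", "pt")])
  tab <- table(factor(one$pt), factor(one$drug_group, levels = drugs))
  ok <- rownames(tab)[apply(tab >= min_cases, 1, all)]
  sort(ok)
}

#' Disproportionality analysis versus a comparator
#'
#' One ROR with Woolf CI per (drug of interest x target): the nine ADR event
#' groups and every eligible preferred term, each newer drug against the
#' comparator. Zero-cell results are flagged `defined = FALSE`, not
#' dropped. Significance means the CI excludes 1 (equivalent to p < 0.05
#' under the normal approximation); no multiplicity adjustment is applied.
#'
#' @param assignments Output of [assign_groups()] for all drugs.
#' @param comparator Reference drug (default `"glatiramer"`).
#' @param drugs Drugs of interest (default: the four DMTs, minus the
#'   comparator).
#' @param alpha Two-sided level for the CI (default 0.05).
#' @param min_cases Term eligibility threshold (default 3).
#' @return Data frame with one row per result: `level` ("group"/"pt"),
#'   `target`, `drug`, `comparator`, `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high` (unrounded), `defined`, `eligible`, `significant`.
#' @export
run_disproportionality <- function(assignments, comparator = "glatiramer",
                                   drugs = NULL, alpha = 0.05,
                                   min_cases = 3) {
  present <- unique(assignments$drug_group)
  if (!comparator %in% present) {
    stop("comparator drug absent from the data: ", comparator, call. = FALSE)
  }
  if (is.null(drugs)) drugs <- setdiff(intersect(dmt_drugs(), present),
                                       comparator)
  if (length(drugs) == 0) {
    stop("no drug of interest besides the comparator", call. = FALSE)
  }
  all_drugs <- c(drugs, comparator)
  counts <- group_counts(assignments, drugs = all_drugs)
  totals <- vapply(all_drugs, function(d) sum(counts$groups[[d]]),
                   numeric(1))
  elig <- eligible_pts(assignments, drugs = all_drugs,
                       min_cases = min_cases)
  pt_counts <- stats::aggregate(
    list(n = rep(1L, nrow(assignments))),
    by = list(pt = assignments$pt, drug_group = assignments$drug_group),
    FUN = sum)
  one_row <- function(level, target, drug, tab) {
    ror <- compute_ror(tab)
    ci <- woolf_ci(tab, alpha)
    data.frame(level = level, target = target, drug = drug,
               comparator = comparator, a = tab$a, b = tab$b, c = tab$c,
               d = tab$d, ror = ror, ci_low = ci[["low"]],
               ci_high = ci[["high"]], defined = !is.na(ror),
               eligible = TRUE,
               significant = !is.na(ror) &&
                 (ci[["low"]] > 1 || ci[["high"]] < 1),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (drug in drugs) {
    for (g in adr_group_names()) {
      tab <- build_contingency(counts$groups, g, drug, comparator,
                               totals = totals)
      rows[[length(rows) + 1]] <- one_row("group", g, drug, tab)
    }
    for (p in elig) {
      a <- sum(pt_counts$n[pt_counts$pt == p & pt_counts$drug_group == drug])
      c_ <- sum(pt_counts$n[pt_counts$pt == p &
                              pt_counts$drug_group == comparator])
      tab <- list(target = p, drug = drug, comparator = comparator,
                  a = a, b = totals[[drug]] - a, c = c_,
                  d = totals[[comparator]] - c_)
      rows[[length(rows) + 1]] <- one_row("pt", p, drug, tab)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Text forest table
#'
#' Plain-text rendering of a disproportionality result set, rounded to two
#' decimals at reporting time (half-up, as published).
#'
#' @param res Output of [run_disproportionality()].
#' @return Character vector of lines.
#' @export
forest_text <- function(res) {
  fmt <- function(x) ifelse(is.na(x), "   NE", sprintf("%5.2f",
                                                       round_half_up(x, 2)))
  header <- sprintf("%-34s %-12s %9s %13s %4s", "target", "drug", "ROR",
                    "95% CI", "sig")
  lines <- sprintf("%-34s %-12s %9s  %s-%s %4s",
                   substr(res$target, 1, 34), res$drug, fmt(res$ror),
                   fmt(res$ci_low), fmt(res$ci_high),
                   ifelse(res$significant, "*", ""))
  c(header, lines)
}
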