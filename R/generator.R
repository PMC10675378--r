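## Stochastic report generator. Emulates the selected pregnancy/lactation
## case set: per-drug case volumes, events per case, term frequencies,
## exposure/reporter/region mixtures and seriousness/outcome mixtures all
## default to the published marginals. Optional planted fractions add cases
## that the selection step must reject (paternal exposure, adult-age
## conflicts, no matching keyword at all), with truth labels for every case
## and event so selection and grouping can be scored against the plant.

props <- function(counts) {
  x <- unlist(counts)
  if (sum(x) == 0) x else x / sum(x)
}

#' Default generator configuration
#'
#' Parameterised from the published marginal tables: per-drug case counts
#' 839/201/100/96, mean events per case equal to the per-drug event/case
#' ratios (2.9 overall), term frequencies proportional to the group table
#' (with one pooled synthetic term per group for the unprinted remainder),
#' and categorical mixtures matching the characteristics and
#' seriousness/outcome tables. Planted-rejection fractions default to 0:
#' the generator emulates the *selected* set unless plants are requested.
#'
#' @param seed Root seed; per-drug substreams are derived from it and the
#'   drug name, so adding a drug does not perturb the draws of the others.
#' @return An object of class `synth_config`.
#' @export
default_config <- function(seed = 1L) {
  sc <- study_counts()
  drugs <- sc$drug_order
  per_drug <- lapply(seq_along(drugs), function(di) {
    pool <- drug_event_pool(sc, di)
    agg <- stats::aggregate(list(weight = rep(1L, nrow(pool))),
                            by = list(pt = pool$pt, group = pool$group),
                            FUN = sum)
    ## pool the numbered placeholders into one synthetic term per group
    synth <- grepl("(synthetic", agg$pt, fixed = TRUE)
    agg$pt[synth] <- vapply(agg$group[synth], function(g) {
      sprintf("%s (synthetic pool)", group_placeholder_label()[[g]])
    }, character(1))
    pt_table <- stats::aggregate(list(weight = agg$weight),
                                 by = list(pt = agg$pt, group = agg$group),
                                 FUN = sum)
    ## non-ADR coding beyond the one seed exposure term per case
    non_adr_extra <- max(0, sc$events[di] - sum(pt_table$weight) -
                           sc$cases[di])
    if (non_adr_extra > 0) {
      pt_table <- rbind(pt_table,
                        data.frame(pt = "Drug exposure during pregnancy",
                                   group = "not_indicating_adr",
                                   weight = non_adr_extra))
    }
    list(
      n_cases = sc$cases[di],
      mean_events = sc$events[di] / sc$cases[di],
      pt_table = pt_table,
      exposure_probs = props(lapply(sc$table1$exposure, `[[`, di)),
      child_probs = props(c(lapply(sc$table1$child_age, `[[`, di),
                            none = sc$cases[di] -
                              sum(vapply(sc$table1$child_age, `[[`,
                                         numeric(1), di)))),
      baby_sex_probs = props(lapply(sc$table1$baby_sex, `[[`, di)),
      mother_age_probs = props(c(
        "12_17" = sc$table1$mother_age[["12_17"]][di],
        "18_64" = sc$table1$mother_age[["18_64"]][di],
        not_specified = sc$table1$age_not_specified[di])),
      reporter_probs = props(lapply(sc$table1$reporter, `[[`, di)),
      region_probs = props(lapply(sc$table1$region, `[[`, di)),
      criteria_probs = props(lapply(sc$table3$seriousness, `[[`, di)),
      outcome_probs = props(lapply(sc$table3$outcome, `[[`, di)))
  })
  names(per_drug) <- drugs
  structure(list(drugs = per_drug,
                 inclusion_miss_fraction = 0,
                 paternal_fraction = 0,
                 adult_conflict_fraction = 0,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d drugs, seed %d, planted fractions %.3f/%.3f/%.3f\n",
              length(x$drugs), x$seed, x$inclusion_miss_fraction,
              x$paternal_fraction, x$adult_conflict_fraction))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  for (d in names(cfg$drugs)) {
    dc <- cfg$drugs[[d]]
    if (dc$n_cases < 0 || dc$mean_events < 1) {
      stop("invalid case/event configuration for ", d, call. = FALSE)
    }
    for (p in grep("_probs$", names(dc), value = TRUE)) {
      v <- dc[[p]]
      if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
        stop(sprintf("probabilities '%s' for %s must sum to 1", p, d),
             call. = FALSE)
      }
    }
    if (any(dc$pt_table$weight < 0) || sum(dc$pt_table$weight) <= 0) {
      stop("invalid term weights for ", d, call. = FALSE)
    }
  }
  fr <- cfg$inclusion_miss_fraction + cfg$paternal_fraction +
    cfg$adult_conflict_fraction
  if (fr < 0 || fr > 1) stop("planted fractions must lie in [0,1]",
                             call. = FALSE)
  invisible(cfg)
}

## Deterministic per-drug substream seed from the root seed and drug name;
## kept below 2^31.
substream_seed <- function(seed, drug) {
  h <- sum(utf8ToInt(drug) * seq_along(utf8ToInt(drug)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

subject_of_group <- c(foetal_other = "foetus", neonatal_other = "neonate",
                      infant_other = "infant", maternal_other = "mother")

sample_level <- function(p, n = 1) {
  sample(names(p), n, replace = TRUE, prob = p)
}

generate_one_drug <- function(drug, dc, cfg, resource) {
  set.seed(substream_seed(cfg$seed, drug))
  n <- dc$n_cases
  if (n == 0) return(NULL)
  plant_p <- c(none = 1 - cfg$inclusion_miss_fraction -
                 cfg$paternal_fraction - cfg$adult_conflict_fraction,
               inclusion_miss = cfg$inclusion_miss_fraction,
               paternal_exposure = cfg$paternal_fraction,
               adult_age_conflict = cfg$adult_conflict_fraction)
  plant <- sample_level(plant_p, n)
  child <- sample_level(dc$child_probs, n)
  exposure <- sample_level(dc$exposure_probs, n)
  reporter <- sample_level(dc$reporter_probs, n)
  region <- sample_level(dc$region_probs, n)
  mother <- ifelse(child == "none", sample_level(dc$mother_age_probs, n),
                   NA_character_)
  baby <- ifelse(child != "none", sample_level(dc$baby_sex_probs, n),
                 NA_character_)
  case_id <- sprintf("SYN-%s-%06d", toupper(substr(drug, 1, 3)), seq_len(n))
  n_extra <- stats::rpois(n, max(dc$mean_events - 1, 0))

  pt_tab <- dc$pt_table
  pt_tab$wording <- vapply(pt_tab$pt, function(p) {
    s <- infer_subject(p, "none")
    if (s == "mother" && !grepl("maternal|mother", norm_term(p))) "none"
    else s
  }, character(1))
  worded_smq <- pt_tab[pt_tab$group %in% smq_group_names() &
                         vapply(pt_tab$pt, function(p) {
                           match_inclusion(p)$match
                         }, logical(1)), , drop = FALSE]
  rows_for_case <- function(ci, k) {
    if (k == 0) return(NULL)
    tab <- pt_tab
    keep <- vapply(seq_len(nrow(tab)), function(r) {
      if (tab$group[r] == "not_indicating_adr") {
        ## extra exposure coding must not contradict the case's class
        return(exposure[ci] == "during_pregnancy_or_transplacental")
      }
      if (tab$group[r] %in% smq_group_names()) return(TRUE)
      subj <- if (tab$wording[r] != "none") tab$wording[r] else
        switch(child[ci], foetus = "foetus", neonate_0_1m = "neonate",
               infant_2m_2y = "infant", "mother")
      identical(subject_of_group[[tab$group[r]]], subj)
    }, logical(1))
    tab <- tab[keep, , drop = FALSE]
    idx <- sample.int(nrow(tab), k, replace = TRUE, prob = tab$weight)
    tab[idx, c("pt", "group"), drop = FALSE]
  }

  cases_ev <- vector("list", n)
  exposure_lab <- exposure
  for (i in seq_len(n)) {
    if (plant[i] == "inclusion_miss") {
      pts <- data.frame(pt = sample(c("Headache", "Nausea", "Pyrexia"),
                                    1 + n_extra[i] %% 2, replace = TRUE),
                        group = "maternal_other", stringsAsFactors = FALSE)
      exposure_lab[i] <- NA_character_
    } else if (plant[i] == "paternal_exposure") {
      pts <- data.frame(pt = c("Paternal drug exposure",
                               "Congenital anomaly"),
                        group = c("not_indicating_adr",
                                  "congenital_familial_genetic"),
                        stringsAsFactors = FALSE)
      exposure_lab[i] <- NA_character_
    } else if (plant[i] == "adult_age_conflict") {
      pts <- data.frame(pt = "Premature menopause",
                        group = "maternal_other", stringsAsFactors = FALSE)
      exposure_lab[i] <- NA_character_
    } else {
      seed <- if (exposure[i] == "not_specified") {
        j <- sample.int(nrow(worded_smq), 1, prob = worded_smq$weight)
        worded_smq[j, c("pt", "group"), drop = FALSE]
      } else {
        data.frame(pt = exposure_seed_pt[[exposure[i]]],
                   group = "not_indicating_adr", stringsAsFactors = FALSE)
      }
      pts <- rbind(seed, rows_for_case(i, n_extra[i]))
    }
    cases_ev[[i]] <- pts
  }

  n_ev <- vapply(cases_ev, nrow, integer(1))
  crit <- sample_level(dc$criteria_probs, sum(n_ev))
  outc <- ifelse(crit == "death", "fatal",
                 sample_level(props(dc$outcome_probs[
                   setdiff(names(dc$outcome_probs), "fatal")]), sum(n_ev)))
  ev_case_idx <- rep(seq_len(n), n_ev)
  events <- data.frame(
    drug_group = drug, case_id = case_id[ev_case_idx],
    event_index = unlist(lapply(n_ev, seq_len)),
    pt = unlist(lapply(cases_ev, `[[`, "pt")), duration = "",
    outcome = outc, seriousness = crit, subject = "unspecified",
    stringsAsFactors = FALSE)
  cases <- data.frame(
    drug_group = drug, case_id = case_id, report_type = "spontaneous",
    reporter = reporter, region = region, mother_age_group = mother,
    child_age_group = child, baby_sex = baby, stringsAsFactors = FALSE)
  route <- ifelse(plant == "none" &
                    exposure == "during_pregnancy_or_transplacental",
                  "Transplacental", "")
  drugs <- data.frame(drug_group = drug, case_id = case_id, name = drug,
                      role = "suspect", route = route,
                      stringsAsFactors = FALSE)
  true_group <- unlist(lapply(cases_ev, `[[`, "group"))
  list(cases = cases, drugs = drugs, events = events,
       case_labels = data.frame(
         drug_group = drug, case_id = case_id,
         include = plant == "none",
         reason = ifelse(plant == "none", NA_character_, plant),
         exposure_class = exposure_lab, stringsAsFactors = FALSE),
       event_labels = data.frame(
         drug_group = drug, case_id = case_id[ev_case_idx],
         event_index = events$event_index, group = true_group,
         stringsAsFactors = FALSE))
}

#' Generate a synthetic labelled case set
#'
#' Draws a reproducible case collection under a [default_config()]-style
#' configuration. Every generated case passes the ICSR invariants, and the
#' truth labels (selection decision with reason, exposure class, event
#' group) are consistent with the sampled terms by construction.
#'
#' @param config A `synth_config` (default [default_config()]).
#' @return A `labelled_case_set` (see [fixture_exact_counts()]).
#' @export
generate_cases <- function(config = default_config()) {
  validate_config(config)
  resource <- smq_resource()
  parts <- Filter(Negate(is.null),
                  lapply(names(config$drugs), function(d) {
                    generate_one_drug(d, config$drugs[[d]], config, resource)
                  }))
  if (length(parts) == 0) {
    out <- list(cases = empty_icsr_set(),
                case_labels = data.frame(), event_labels = data.frame())
    class(out) <- "labelled_case_set"
    return(out)
  }
  out <- list(
    cases = icsr_set(do.call(rbind, lapply(parts, `[[`, "cases")),
                     do.call(rbind, lapply(parts, `[[`, "drugs")),
                     do.call(rbind, lapply(parts, `[[`, "events"))),
    case_labels = do.call(rbind, lapply(parts, `[[`, "case_labels")),
    event_labels = do.call(rbind, lapply(parts, `[[`, "event_labels")))
  class(out) <- "labelled_case_set"
  out
}
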