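#' Selection vocabulary
#'
#' Loads the pregnancy/lactation selection terms: exact exposure preferred
#' terms, the retrieval word list, route-of-administration terms, and the
#' exclusion lists (paternal exposure; adult-condition terms that the word
#' search pulls in). All terms are lower-cased and de-duplicated.
#'
#' @param path Optional path to a terms YAML; default is the packaged
#'   resource.
#' @return An object of class `selection_terms`.
#' @export
selection_terms <- function(path = NULL) {
  cfg <- if (is.null(path)) read_resource("selection_terms.yaml") else
    yaml::read_yaml(path)
  need <- c("inclusion_pt_exact", "inclusion_pt_substrings",
            "inclusion_route_terms", "exclusion_paternal_substrings",
            "exclusion_adult_conflict_terms")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("selection terms resource is missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cfg <- lapply(cfg, function(x) unique(norm_term(unlist(x))))
  if (any(vapply(cfg, function(x) any(!nzchar(x)), logical(1)))) {
    stop("empty selection term", call. = FALSE)
  }
  structure(cfg[need], class = "selection_terms")
}

match_any_substring <- function(text, terms) {
  hits <- terms[vapply(terms, function(tm) grepl(tm, text, fixed = TRUE),
                       logical(1))]
  hits
}

## Inclusion evidence of one case, split by kind so the exclusion rule can
## ask whether anything besides an adult-conflict word match is present.
inclusion_evidence <- function(pts, routes, terms) {
  pts_n <- norm_term(pts)
  routes_n <- norm_term(routes)
  exact <- pts[pts_n %in% terms$inclusion_pt_exact]
  sub_hits <- lapply(pts_n, match_any_substring,
                     terms = terms$inclusion_pt_substrings)
  word <- unique(unlist(sub_hits))
  route <- unique(routes[routes_n %in% terms$inclusion_route_terms])
  list(exact = unique(exact), words = word, routes = route,
       word_pts = pts[lengths(sub_hits) > 0])
}

#' Inclusion match for one case
#'
#' A case is retrieved when any event preferred term matches an exact
#' exposure term or contains one of the retrieval words, or any drug
#' mention's route of administration is a pregnancy/lactation route
#' (transplacental, transmammary, maternal exposure timing unspecified).
#'
#' @param pts Character vector of the case's event preferred terms.
#' @param routes Character vector of the case's drug routes (may be empty).
#' @param terms A [selection_terms()] object.
#' @return List with `match` (logical) and `matched_terms` (character, for
#'   the audit trail).
#' @export
match_inclusion <- function(pts, routes = character(),
                            terms = selection_terms()) {
  ev <- inclusion_evidence(pts, routes, terms)
  matched <- unique(c(ev$exact, ev$words, ev$routes))
  list(match = length(matched) > 0, matched_terms = matched)
}

#' Exclusion rules for one retrieved case
#'
#' Two published exclusions: reports of paternal drug exposure, and reports
#' where a child-related retrieval word actually described the adult patient.
#' The second is operationalised as a list of adult-condition terms that
#' fires only when the case carries no other pregnancy/lactation evidence
#' (no exposure preferred term, no exposure route, no other word match).
#'
#' @param pts,routes,terms As in [match_inclusion()].
#' @return List with `keep` (logical) and `reason` (`NA`,
#'   `"paternal_exposure"` or `"adult_age_conflict"`).
#' @export
apply_exclusions <- function(pts, routes = character(),
                             terms = selection_terms()) {
  pts_n <- norm_term(pts)
  pat <- any(vapply(terms$exclusion_paternal_substrings, function(tm) {
    any(grepl(tm, pts_n, fixed = TRUE))
  }, logical(1)))
  if (pat) return(list(keep = FALSE, reason = "paternal_exposure"))
  conflict_pt <- vapply(pts_n, function(p) {
    any(vapply(terms$exclusion_adult_conflict_terms, grepl, logical(1),
               x = p, fixed = TRUE))
  }, logical(1))
  if (any(conflict_pt)) {
    ev <- inclusion_evidence(pts, routes, terms)
    other_evidence <- length(ev$exact) > 0 || length(ev$routes) > 0 ||
      length(setdiff(ev$word_pts, pts[conflict_pt])) > 0
    if (!other_evidence) {
      return(list(keep = FALSE, reason = "adult_age_conflict"))
    }
  }
  list(keep = TRUE, reason = NA_character_)
}

exposure_pt_classes <- function() {
  list(
    during_pregnancy_or_transplacental = c(
      "maternal exposure during pregnancy", "foetal exposure during pregnancy",
      "exposure during pregnancy", "exposure in utero",
      "drug exposure during pregnancy"),
    breastfeeding_or_transmammary = c(
      "exposure via breast milk", "drug exposure via breast milk",
      "maternal exposure during breast feeding", "exposure during breastfeeding"),
    before_pregnancy = c(
      "maternal exposure before pregnancy", "drug exposure before pregnancy"),
    timing_unspecified = c(
      "maternal exposure timing unspecified", "foetal exposure timing unspecified"))
}

#' Exposure-type classification of a selected case
#'
#' Assigns exactly one exposure class per case from its exposure preferred
#' terms and drug routes, in priority order: during pregnancy >
#' breastfeeding > before pregnancy > timing unspecified > not specified.
#' A route is consulted only when no exposure term decides the class
#' (transplacental counts as during-pregnancy, transmammary as
#' breastfeeding).
#'
#' @param pts,routes As in [match_inclusion()].
#' @return One of [exposure_class_levels()].
#' @export
classify_exposure <- function(pts, routes = character()) {
  pts_n <- norm_term(pts)
  routes_n <- norm_term(routes)
  classes <- exposure_pt_classes()
  for (cl in names(classes)) {
    if (any(pts_n %in% classes[[cl]])) return(cl)
  }
  if (any(routes_n == "transmammary")) return("breastfeeding_or_transmammary")
  if (any(routes_n == "transplacental")) {
    return("during_pregnancy_or_transplacental")
  }
  if (any(routes_n == "maternal exposure timing unspecified")) {
    return("timing_unspecified")
  }
  "not_specified"
}

#' Select pregnancy/lactation cases
#'
#' The two-step selection: keyword/route inclusion, then exclusion of
#' paternal-exposure and adult-age-conflict reports. Every selected case is
#' annotated with its exposure class; the audit reconciles all counts per
#' drug (retrieved = included + inclusion miss + excluded by rule).
#'
#' @param x An `icsr_set` (the merged retrieval).
#' @param terms A [selection_terms()] object.
#' @return List with `selected` (an `icsr_set` whose `cases` gain an
#'   `exposure_class` column), `audit` (per-drug count reconciliation) and
#'   `case_log` (per-case decision, matched terms, exclusion reason).
#' @export
select_cases <- function(x, terms = selection_terms()) {
  stopifnot(inherits(x, "icsr_set"))
  cs <- x$cases
  audit_cols <- c("retrieved", "included", "excluded_inclusion_miss",
                  "excluded_paternal_exposure", "excluded_adult_age_conflict")
  if (nrow(cs) == 0) {
    audit <- data.frame(drug_group = character(),
                        matrix(integer(), 0, length(audit_cols),
                               dimnames = list(NULL, audit_cols)))
    sel <- empty_icsr_set()
    sel$cases$exposure_class <- character()
    return(list(selected = sel, audit = audit,
                case_log = data.frame()))
  }
  key <- case_key(cs)
  ekey <- case_key(x$events)
  dkey <- case_key(x$drugs)
  pts_by <- split(x$events$pt, factor(ekey, levels = key))
  routes_by <- split(x$drugs$route[x$drugs$role != "concomitant"],
                     factor(dkey[x$drugs$role != "concomitant"],
                            levels = key))
  decision <- lapply(seq_along(key), function(i) {
    pts <- pts_by[[i]]
    routes <- routes_by[[i]] %||% character()
    routes <- routes[nzchar(routes)]
    inc <- match_inclusion(pts, routes, terms)
    if (!inc$match) {
      return(list(status = "inclusion_miss", matched = character(),
                  class = NA_character_))
    }
    exc <- apply_exclusions(pts, routes, terms)
    if (!exc$keep) {
      return(list(status = exc$reason, matched = inc$matched_terms,
                  class = NA_character_))
    }
    list(status = "included", matched = inc$matched_terms,
         class = classify_exposure(pts, routes))
  })
  status <- vapply(decision, `[[`, character(1), "status")
  case_log <- data.frame(
    drug_group = cs$drug_group, case_id = cs$case_id, status = status,
    matched_terms = vapply(decision, function(d) {
      paste(d$matched, collapse = "; ")
    }, character(1)),
    stringsAsFactors = FALSE)
  keep <- status == "included"
  sel <- subset_cases(x, key[keep])
  sel$cases$exposure_class <-
    vapply(decision[match(case_key(sel$cases), key)], `[[`, character(1),
           "class")
  tab <- function(st) {
    as.integer(table(factor(cs$drug_group[status == st],
                            levels = unique(cs$drug_group))))
  }
  audit <- data.frame(
    drug_group = unique(cs$drug_group),
    retrieved = as.integer(table(factor(cs$drug_group,
                                        levels = unique(cs$drug_group)))),
    included = tab("included"),
    excluded_inclusion_miss = tab("inclusion_miss"),
    excluded_paternal_exposure = tab("paternal_exposure"),
    excluded_adult_age_conflict = tab("adult_age_conflict"),
    stringsAsFactors = FALSE)
  stopifnot(all(audit$retrieved == audit$included +
                  audit$excluded_inclusion_miss +
                  audit$excluded_paternal_exposure +
                  audit$excluded_adult_age_conflict))
  list(selected = sel, audit = audit, case_log = case_log)
}
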