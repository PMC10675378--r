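#' Event-group term resource
#'
#' Loads the term lists behind the ten event groups: the five
#' pregnancy-and-neonatal SMQ subtopics and the terms not indicating an ADR
#' (exposure coding, predisposing conditions). Within the resource a
#' preferred term may belong to at most one subtopic list. Synthetic
#' placeholder terms (standing in for non-public appendix detail) are
#' recognised by prefix.
#'
#' @param path Optional path to a resource YAML; default is the packaged
#'   list.
#' @return An object of class `smq_resource`.
#' @export
smq_resource <- function(path = NULL) {
  cfg <- if (is.null(path)) read_resource("smq_groups.yaml") else
    yaml::read_yaml(path)
  if (!all(smq_group_names() %in% names(cfg$groups))) {
    stop("resource must define all five SMQ subtopic groups", call. = FALSE)
  }
  terms <- lapply(cfg$groups, function(g) norm_term(unlist(g$terms)))
  all_terms <- unlist(terms)
  if (anyDuplicated(all_terms) > 0) {
    stop("preferred term in more than one SMQ subtopic list: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    version = cfg$version %||% "unversioned",
    scope = cfg$scope %||% "unstated",
    terms = terms,
    prefixes = lapply(cfg$groups, function(g) {
      norm_term(unlist(g$placeholder_prefixes %||% character()))
    }),
    non_adr_terms = norm_term(unlist(cfg$not_indicating_adr$terms)),
    non_adr_prefixes = norm_term(unlist(
      cfg$not_indicating_adr$placeholder_prefixes %||% character()))),
    class = "smq_resource")
}

#' @export
print.smq_resource <- function(x, ...) {
  cat(sprintf("<smq_resource> version %s (%d subtopic terms, %d non-ADR terms)\n",
              x$version, length(unlist(x$terms)), length(x$non_adr_terms)))
  invisible(x)
}

subject_wording_hints <- function() {
  list(foetus = c("foetal", "foetus", "in utero"),
       neonate = c("neonatal", "neonate", "newborn", "of newborn"),
       infant = c("infant", "infantile"),
       mother = c("maternal", "mother"))
}

#' Infer the subject of one event
#'
#' Who experienced the event: the foetus, the neonate, the infant, or the
#' pregnant/lactating woman. Explicit wording in the preferred term is
#' preferred over the case-level child age field; a case with no child
#' involved defaults to the mother.
#'
#' @param pt Preferred term text.
#' @param child_age_group The case's child age group
#'   (one of [child_age_levels()]).
#' @return One of `"mother"`, `"foetus"`, `"neonate"`, `"infant"`.
#' @export
infer_subject <- function(pt, child_age_group = "none") {
  p <- norm_term(pt)
  for (subj in names(subject_wording_hints())) {
    if (any(vapply(subject_wording_hints()[[subj]], grepl, logical(1),
                   x = p, fixed = TRUE))) {
      return(subj)
    }
  }
  switch(child_age_group,
         foetus = "foetus", neonate_0_1m = "neonate",
         infant_2m_2y = "infant", "mother")
}

matches_group_list <- function(pt_n, terms, prefixes) {
  pt_n %in% terms || any(vapply(prefixes, startsWith, logical(1), x = pt_n))
}

#' Assign one event to its event group
#'
#' Precedence: terms not indicating an ADR first (exposure coding,
#' predisposing conditions), then the five SMQ subtopic lists, else the
#' subject-specific "other ADRs" group.
#'
#' @param pt Preferred term text.
#' @param subject Subject from [infer_subject()].
#' @param resource A [smq_resource()].
#' @return One of [event_groups()].
#' @export
assign_event_group <- function(pt, subject, resource = smq_resource()) {
  pt_n <- norm_term(pt)
  if (matches_group_list(pt_n, resource$non_adr_terms,
                         resource$non_adr_prefixes)) {
    return("not_indicating_adr")
  }
  for (g in smq_group_names()) {
    if (matches_group_list(pt_n, resource$terms[[g]], resource$prefixes[[g]])) {
      return(g)
    }
  }
  switch(subject,
         foetus = "foetal_other", neonate = "neonatal_other",
         infant = "infant_other", mother = "maternal_other",
         {
           warning(sprintf("unresolvable subject for '%s'; defaulting to maternal",
                           pt), call. = FALSE)
           "maternal_other"
         })
}

#' Assign every event of a selected case set
#'
#' @param x A selected `icsr_set`.
#' @param resource A [smq_resource()].
#' @return Data frame (one row per event): `drug_group`, `case_id`,
#'   `event_index`, `pt`, `subject`, `group`. The assignment is a partition:
#'   exactly one group per event, independent of input order.
#' @export
assign_groups <- function(x, resource = smq_resource()) {
  stopifnot(inherits(x, "icsr_set"))
  ev <- x$events
  child <- x$cases$child_age_group[match(case_key(ev), case_key(x$cases))]
  subj <- vapply(seq_len(nrow(ev)), function(i) {
    infer_subject(ev$pt[i], child[i])
  }, character(1))
  grp <- vapply(seq_len(nrow(ev)), function(i) {
    assign_event_group(ev$pt[i], subj[i], resource)
  }, character(1))
  data.frame(drug_group = ev$drug_group, case_id = ev$case_id,
             event_index = ev$event_index, pt = ev$pt, subject = subj,
             group = grp, stringsAsFactors = FALSE)
}

#' Event counts by group and preferred term
#'
#' @param assignments Output of [assign_groups()].
#' @param drugs Drug order for the count columns (default the four DMTs
#'   present).
#' @return List with `groups` (per-drug counts per group, all ten groups,
#'   plus a `total` column) and `pts` (per-drug counts per group x preferred
#'   term). Group counts sum to the per-drug event totals.
#' @export
group_counts <- function(assignments, drugs = NULL) {
  if (is.null(drugs)) {
    drugs <- intersect(dmt_drugs(), unique(assignments$drug_group))
    if (length(drugs) == 0) drugs <- unique(assignments$drug_group)
  }
  if (nrow(assignments) == 0) {
    groups <- data.frame(group = event_groups(), stringsAsFactors = FALSE)
    for (d in drugs) groups[[d]] <- 0L
    groups$total <- 0L
    pts <- data.frame(group = character(), pt = character(),
                      stringsAsFactors = FALSE)
    for (d in drugs) pts[[d]] <- integer()
    pts$total <- integer()
    return(list(groups = groups, pts = pts))
  }
  gf <- factor(assignments$group, levels = event_groups())
  df <- factor(assignments$drug_group, levels = drugs)
  gtab <- table(gf, df)
  groups <- data.frame(group = event_groups(),
                       as.data.frame.matrix(gtab),
                       stringsAsFactors = FALSE, check.names = FALSE)
  groups$total <- rowSums(gtab)
  rownames(groups) <- NULL
  ptab <- stats::aggregate(
    list(n = rep(1L, nrow(assignments))),
    by = list(group = assignments$group, pt = assignments$pt,
              drug_group = assignments$drug_group), FUN = sum)
  pts <- stats::reshape(ptab, direction = "wide",
                        idvar = c("group", "pt"), timevar = "drug_group")
  names(pts) <- sub("^n\\.", "", names(pts))
  for (d in drugs) if (!d %in% names(pts)) pts[[d]] <- 0L
  pts <- pts[, c("group", "pt", drugs)]
  pts[is.na(pts)] <- 0L
  pts$total <- rowSums(pts[, drugs, drop = FALSE])
  pts <- pts[order(match(pts$group, event_groups()), -pts$total, pts$pt), ]
  rownames(pts) <- NULL
  list(groups = groups, pts = pts)
}
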