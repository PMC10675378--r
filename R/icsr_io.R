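#' Empty ICSR collection
#'
#' @return An `icsr_set` with zero cases.
#' @export
empty_icsr_set <- function() {
  icsr_set(
    cases = data.frame(drug_group = character(), case_id = character(),
                       report_type = character(), reporter = character(),
                       region = character(), mother_age_group = character(),
                       child_age_group = character(), baby_sex = character(),
                       stringsAsFactors = FALSE),
    drugs = data.frame(drug_group = character(), case_id = character(),
                       name = character(), role = character(),
                       route = character(), stringsAsFactors = FALSE),
    events = data.frame(drug_group = character(), case_id = character(),
                        event_index = integer(), pt = character(),
                        duration = character(), outcome = character(),
                        seriousness = character(), subject = character(),
                        stringsAsFactors = FALSE),
    validate = FALSE)
}

read_ll_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
}

#' Read an ICSR line listing
#'
#' Reads a per-drug export in either the packed dialect (one row per case,
#' reactions in one cell) or the long dialect (one row per event). The
#' format is detected from the columns present.
#'
#' @param path CSV file path.
#' @param drug_group Drug of interest the export belongs to; required when
#'   the file carries no drug-group column, otherwise optional (a mismatch
#'   is an error).
#' @param dialect A [ev_dialect()] object.
#' @return A validated [icsr_set()].
#' @export
read_line_listing <- function(path, drug_group = NULL,
                              dialect = ev_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read_ll_csv(path)
  cols <- dialect$columns
  lcols <- dialect$long_columns
  packed <- cols$reactions %in% names(raw)
  need <- unlist(cols[setdiff(names(cols), c("drug_group",
                                             if (!packed) "reactions"))])
  if (!packed) need <- c(need, unlist(lcols[c("pt", "outcome",
                                              "seriousness")]))
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("line listing is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_dg <- cols$drug_group %in% names(raw)
  if (!has_dg && is.null(drug_group)) {
    stop("file has no drug-group column; supply drug_group", call. = FALSE)
  }
  dg <- if (has_dg) raw[[cols$drug_group]] else rep(drug_group, nrow(raw))
  if (has_dg && !is.null(drug_group) && any(dg != drug_group)) {
    stop("file drug group disagrees with the drug_group argument",
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_icsr_set())

  grab <- function(field) {
    v <- raw[[cols[[field]]]]
    if (is.null(v)) rep("", nrow(raw)) else v
  }
  if (packed) {
    cases <- data.frame(
      drug_group = dg, case_id = grab("case_id"),
      report_type = grab("report_type"), reporter = grab("reporter"),
      region = grab("region"), mother_age_group = grab("mother_age_group"),
      child_age_group = grab("child_age_group"), baby_sex = grab("baby_sex"),
      stringsAsFactors = FALSE)
    ev_list <- lapply(seq_len(nrow(raw)), function(i) {
      ev <- parse_reaction_list(raw[[cols$reactions]][i], dialect)
      if (nrow(ev) > 0) {
        cbind(data.frame(drug_group = dg[i], case_id = cases$case_id[i],
                         event_index = seq_len(nrow(ev)),
                         stringsAsFactors = FALSE), ev)
      }
    })
    events <- do.call(rbind, ev_list)
    if (is.null(events)) events <- empty_icsr_set()$events
    drug_list <- lapply(seq_len(nrow(raw)), function(i) {
      d <- rbind(parse_drug_list(grab("suspect_drugs")[i], "suspect", dialect),
                 parse_drug_list(grab("concomitant_drugs")[i], "concomitant",
                                 dialect))
      if (nrow(d) > 0) {
        cbind(data.frame(drug_group = dg[i], case_id = cases$case_id[i],
                         stringsAsFactors = FALSE), d)
      }
    })
    drugs <- do.call(rbind, drug_list)
    if (is.null(drugs)) drugs <- empty_icsr_set()$drugs
  } else {
    lk <- function(field) raw[[lcols[[field]]]]
    events <- data.frame(
      drug_group = dg, case_id = grab("case_id"),
      event_index = as.integer(lk("event_index") %||%
                                 stats::ave(dg, paste(dg, grab("case_id")),
                                            FUN = seq_along)),
      pt = lk("pt"), duration = lk("duration") %||% "",
      outcome = lk("outcome"), seriousness = lk("seriousness"),
      subject = lk("subject") %||% "unspecified", stringsAsFactors = FALSE)
    first <- !duplicated(paste(dg, grab("case_id"), sep = "\r"))
    cases <- data.frame(
      drug_group = dg[first], case_id = grab("case_id")[first],
      report_type = grab("report_type")[first],
      reporter = grab("reporter")[first], region = grab("region")[first],
      mother_age_group = grab("mother_age_group")[first],
      child_age_group = grab("child_age_group")[first],
      baby_sex = grab("baby_sex")[first], stringsAsFactors = FALSE)
    drug_rows <- lapply(which(first), function(i) {
      d <- rbind(parse_drug_list(grab("suspect_drugs")[i], "suspect", dialect),
                 parse_drug_list(grab("concomitant_drugs")[i], "concomitant",
                                 dialect))
      if (nrow(d) > 0) {
        cbind(data.frame(drug_group = dg[i], case_id = grab("case_id")[i],
                         stringsAsFactors = FALSE), d)
      }
    })
    drugs <- do.call(rbind, drug_rows)
    if (is.null(drugs)) drugs <- empty_icsr_set()$drugs
  }
  cases$baby_sex[!nzchar(cases$baby_sex)] <- NA_character_
  cases$mother_age_group[!nzchar(cases$mother_age_group)] <- NA_character_
  events$event_index <- as.integer(events$event_index)
  icsr_set(cases, drugs, events)
}

#' Write an ICSR line listing
#'
#' Inverse of [read_line_listing()]; a written file reads back to an equal
#' collection.
#'
#' @param x An `icsr_set`.
#' @param path Output CSV path.
#' @param dialect A [ev_dialect()] object.
#' @param format `"packed"` (one row per case) or `"long"` (one row per
#'   event).
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(x, path, dialect = ev_dialect(),
                               format = c("packed", "long")) {
  format <- match.arg(format)
  validate_icsr_set(x)
  cols <- dialect$columns
  cs <- x$cases
  key <- case_key(cs)
  dkey <- case_key(x$drugs)
  sus <- vapply(key, function(k) {
    pack_drug_list(x$drugs[dkey == k & x$drugs$role != "concomitant", ,
                           drop = FALSE], dialect)
  }, character(1))
  con <- vapply(key, function(k) {
    pack_drug_list(x$drugs[dkey == k & x$drugs$role == "concomitant", ,
                           drop = FALSE], dialect)
  }, character(1))
  base_df <- data.frame(cs$drug_group, cs$case_id, cs$report_type,
                        cs$reporter, cs$region,
                        ifelse(is.na(cs$mother_age_group), "",
                               cs$mother_age_group),
                        cs$child_age_group,
                        ifelse(is.na(cs$baby_sex), "", cs$baby_sex),
                        sus, con, stringsAsFactors = FALSE)
  names(base_df) <- unlist(cols[c("drug_group", "case_id", "report_type",
                                  "reporter", "region", "mother_age_group",
                                  "child_age_group", "baby_sex",
                                  "suspect_drugs", "concomitant_drugs")])
  ekey <- case_key(x$events)
  if (format == "packed") {
    base_df[[cols$reactions]] <- vapply(key, function(k) {
      pack_reaction_list(x$events[ekey == k, , drop = FALSE], dialect)
    }, character(1))
    out <- base_df
  } else {
    lcols <- dialect$long_columns
    idx <- match(ekey, key)
    out <- base_df[idx, , drop = FALSE]
    ev <- x$events
    out[[lcols$event_index]] <- ev$event_index
    out[[lcols$pt]] <- ev$pt
    out[[lcols$duration]] <- ev$duration
    out[[lcols$outcome]] <- ev$outcome
    out[[lcols$seriousness]] <- ev$seriousness
    out[[lcols$subject]] <- ev$subject
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge per-drug exports
#'
#' Concatenates per-drug collections into one analysis set. A case id
#' occurring in two different drug exports is kept once per drug of
#' interest: the analysis is per drug, so both rows are real observations.
#'
#' @param exports List of `icsr_set` objects, each internally
#'   duplicate-free.
#' @return A single validated `icsr_set`.
#' @export
merge_drug_exports <- function(exports) {
  if (length(exports) == 0) return(empty_icsr_set())
  stopifnot(all(vapply(exports, inherits, logical(1), "icsr_set")))
  merged <- bind_icsr_sets(exports)
  validate_icsr_set(merged)
  merged
}
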