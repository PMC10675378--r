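#' Line-listing dialect
#'
#' A dialect describes how an ICSR line listing is laid out: the map from
#' internal field names to file column headers, and the separators of the
#' packed reaction cell ("PT (duration – outcome – criterion;
#' criterion)" with ", " between events) and of the drug-list cells. The
#' canonical dialect emulating the public per-drug export ships as a YAML
#' resource and round-trips exactly.
#'
#' @param path Optional path to a dialect YAML; default is the packaged
#'   canonical dialect.
#' @return An object of class `ll_dialect`.
#' @export
ev_dialect <- function(path = NULL) {
  cfg <- if (is.null(path)) read_resource("ev_dialect.yaml") else
    yaml::read_yaml(path)
  need <- c("name", "columns", "long_columns", "separators")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("dialect config is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "ll_dialect")
}

#' @export
print.ll_dialect <- function(x, ...) {
  cat(sprintf("<ll_dialect> '%s', %d packed + %d long columns\n",
              x$name, length(x$columns), length(x$long_columns)))
  invisible(x)
}

## Display strings used inside the packed reaction cell.
outcome_display <- c(
  recovered_resolved = "Recovered/Resolved",
  recovering_resolving = "Recovering/Resolving",
  recovered_with_sequelae = "Recovered/Resolved With Sequelae",
  not_recovered = "Not Recovered/Not Resolved",
  fatal = "Fatal",
  unknown = "Unknown")

criteria_display <- c(
  death = "Results in Death",
  life_threatening = "Life Threatening",
  hospitalisation = "Caused/Prolonged Hospitalisation",
  disabling = "Disabling",
  congenital_anomaly = "Congenital Anomaly",
  other_medically_important = "Other Medically Important Condition",
  none = "Not Serious")

lookup_token <- function(display, map, what, fragment) {
  hit <- names(map)[match(norm_term(display), norm_term(map))]
  if (is.na(hit)) {
    ## degrade rather than reject the whole file: exports vary in quality
    warning(sprintf("unrecognised %s '%s' in '%s'; recorded as %s",
                    what, display, fragment,
                    if (what == "outcome") "unknown" else "none"),
            call. = FALSE)
    hit <- if (what == "outcome") "unknown" else "none"
  }
  hit
}

#' Parse a packed reaction cell
#'
#' Unpacks one reaction-list cell into one row per event. Unknown outcome or
#' seriousness strings degrade to `unknown`/`none` with a warning; a fragment
#' that does not follow the grammar is an error naming the fragment.
#'
#' @param packed The cell text ("" or NA gives zero events).
#' @param dialect A [ev_dialect()] object.
#' @return Data frame with columns `pt`, `duration`, `outcome`,
#'   `seriousness` (";"-joined tokens), `subject` (initialised
#'   "unspecified"), in the packed order.
#' @export
parse_reaction_list <- function(packed, dialect = ev_dialect()) {
  empty <- data.frame(pt = character(), duration = character(),
                      outcome = character(), seriousness = character(),
                      subject = character(), stringsAsFactors = FALSE)
  if (is.null(packed) || is.na(packed) || !nzchar(norm_ws(packed))) {
    return(empty)
  }
  ## events all end with the parenthesised detail block, so the event
  ## boundary ") ," is unambiguous even if a term contains a comma
  frags <- strsplit(norm_ws(packed), ")\\s*,\\s*")[[1]]
  n <- length(frags)
  frags[-n] <- paste0(frags[-n], ")")
  fsep <- dialect$separators$field
  rows <- lapply(frags, function(fr) {
    m <- regmatches(fr, regexec("^(.*)\\((.*)\\)$", fr))[[1]]
    if (length(m) != 3 || !nzchar(norm_ws(m[2]))) {
      stop(sprintf("malformed reaction fragment: '%s'", fr), call. = FALSE)
    }
    parts <- norm_ws(strsplit(m[3], "\u2013")[[1]])
    if (length(parts) != 3) {
      ## a leading empty duration yields an empty first part; anything else
      ## is a grammar violation
      stop(sprintf("malformed reaction detail in: '%s'", fr), call. = FALSE)
    }
    crit_disp <- strsplit(parts[3], dialect$separators$criteria,
                          fixed = TRUE)[[1]]
    crit <- vapply(crit_disp, lookup_token, character(1),
                   map = criteria_display, what = "seriousness criterion",
                   fragment = fr, USE.NAMES = FALSE)
    if (any(crit != "none") && "none" %in% crit) crit <- setdiff(crit, "none")
    data.frame(
      pt = norm_ws(m[2]),
      duration = norm_ws(parts[1]),
      outcome = lookup_token(parts[2], outcome_display, "outcome", fr),
      seriousness = paste(unique(crit), collapse = ";"),
      subject = "unspecified", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pack reaction events into one cell
#'
#' Inverse of [parse_reaction_list()]. Terms may not contain the en-dash
#' field separator or unbalanced parentheses.
#'
#' @param events Data frame with `pt`, `duration`, `outcome`, `seriousness`.
#' @param dialect A [ev_dialect()] object.
#' @return Single cell string ("" for zero events).
#' @export
pack_reaction_list <- function(events, dialect = ev_dialect()) {
  if (nrow(events) == 0) return("")
  if (any(grepl("\u2013", events$pt))) {
    stop("preferred terms may not contain the en-dash field separator",
         call. = FALSE)
  }
  fsep <- dialect$separators$field
  crit <- vapply(split_criteria(events$seriousness), function(s) {
    paste(criteria_display[s], collapse = dialect$separators$criteria)
  }, character(1))
  inner <- paste0(events$duration, fsep, outcome_display[events$outcome],
                  fsep, crit)
  inner <- sub("^\\s+", "", inner)
  paste0(events$pt, " (", inner, ")", collapse = dialect$separators$event)
}

## Drug-list cells: "Name [Route]" joined by the drug separator.
pack_drug_list <- function(drugs, dialect) {
  if (nrow(drugs) == 0) return("")
  entry <- ifelse(nzchar(drugs$route),
                  paste0(drugs$name, " [", drugs$route, "]"), drugs$name)
  paste(entry, collapse = dialect$separators$drug)
}

parse_drug_list <- function(cell, role, dialect) {
  empty <- data.frame(name = character(), role = character(),
                      route = character(), stringsAsFactors = FALSE)
  if (is.null(cell) || is.na(cell) || !nzchar(norm_ws(cell))) return(empty)
  entries <- norm_ws(strsplit(cell, dialect$separators$drug,
                              fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  m <- regmatches(entries, regexec("^(.*?)\\s*\\[(.*)\\]$", entries))
  data.frame(
    name = vapply(seq_along(entries), function(i) {
      if (length(m[[i]]) == 3) m[[i]][2] else entries[i]
    }, character(1)),
    role = role,
    route = vapply(seq_along(entries), function(i) {
      if (length(m[[i]]) == 3) m[[i]][3] else ""
    }, character(1)),
    stringsAsFactors = FALSE)
}
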