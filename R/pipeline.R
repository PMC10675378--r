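#' Pipeline configuration
#'
#' @param input Either `"fixture"` (the exact-count case set),
#'   `"simulate"` (the stochastic generator) or a character vector of
#'   line-listing CSV paths to read.
#' @param out_dir Output directory (created if needed).
#' @param comparator Reference drug for the disproportionality stage.
#' @param alpha Two-sided CI level.
#' @param min_cases Term eligibility threshold.
#' @param seed Seed for `input = "simulate"`.
#' @param terms_path,smq_path,dialect_path Optional overrides of the
#'   packaged resources.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "fixture", out_dir = tempfile("dmtpv-"),
                            comparator = "glatiramer", alpha = 0.05,
                            min_cases = 3, seed = 1L, terms_path = NULL,
                            smq_path = NULL, dialect_path = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_cases >= 0)
  structure(list(input = input, out_dir = out_dir, comparator = comparator,
                 alpha = alpha, min_cases = min_cases, seed = seed,
                 terms_path = terms_path, smq_path = smq_path,
                 dialect_path = dialect_path),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Ingest (or synthesise) the per-drug line listings, select the
#' pregnancy/lactation cases, assign every event to its group, build the
#' three descriptive tables and run the disproportionality analysis. All
#' stage outputs are written as CSV under `config$out_dir` together with a
#' JSON manifest carrying the package version, seed and headline counts,
#' so a bundle can be reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list (`bundle`) with `selected`, `audit`,
#'   `assignments`, `characteristics`, `seriousness_outcome`,
#'   `group_table`, `top_pts`, `ror`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  terms <- selection_terms(config$terms_path)
  resource <- smq_resource(config$smq_path)
  dialect <- ev_dialect(config$dialect_path)

  raw <- if (identical(config$input, "fixture")) {
    fixture_exact_counts()$cases
  } else if (identical(config$input, "simulate")) {
    generate_cases(default_config(seed = config$seed))$cases
  } else {
    merge_drug_exports(lapply(config$input, read_line_listing,
                              dialect = dialect))
  }

  sel <- select_cases(raw, terms)
  assignments <- assign_groups(sel$selected, resource)
  counts <- group_counts(assignments)
  characteristics <- tabulate_characteristics(sel$selected)
  ser_out <- tabulate_seriousness_outcome(sel$selected)
  ror <- run_disproportionality(assignments, comparator = config$comparator,
                                alpha = config$alpha,
                                min_cases = config$min_cases)
  top <- top_pts_per_group(counts, k = 4)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
    name
  }
  files <- c(
    wr(sel$audit, "selection_audit.csv"),
    wr(sel$case_log, "selection_case_log.csv"),
    wr(assignments, "event_assignments.csv"),
    wr(characteristics, "table1_characteristics.csv"),
    wr(counts$groups, "table2_group_counts.csv"),
    wr(top, "table2_top_pts.csv"),
    wr(ser_out, "table3_seriousness_outcome.csv"),
    wr(cbind(ror[, setdiff(names(ror), c("ror", "ci_low", "ci_high"))],
             ror = round_half_up(ror$ror, 2),
             ci_low = round_half_up(ror$ci_low, 2),
             ci_high = round_half_up(ror$ci_high, 2)),
       "ror_results.csv"))
  writeLines(forest_text(ror), file.path(config$out_dir, "ror_forest.txt"))
  files <- c(files, "ror_forest.txt")
  manifest <- list(
    package = "dmtpv",
    version = as.character(utils::packageVersion("dmtpv")),
    input = config$input, seed = config$seed,
    comparator = config$comparator, alpha = config$alpha,
    min_cases = config$min_cases,
    smq_resource_version = resource$version,
    n_cases_retrieved = n_cases(raw),
    n_cases_selected = n_cases(sel$selected),
    n_events_selected = n_events(sel$selected),
    files = files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(selected = sel$selected, audit = sel$audit,
                 assignments = assignments, characteristics = characteristics,
                 seriousness_outcome = ser_out, group_table = counts,
                 top_pts = top, ror = ror, manifest = manifest))
}
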