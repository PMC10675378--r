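#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables round half up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Collapse runs of whitespace and trim; used before any text matching.
norm_ws <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", as.character(x)))
}

norm_term <- function(x) tolower(norm_ws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Read a packaged YAML resource from inst/extdata.
read_resource <- function(name) {
  path <- system.file("extdata", name, package = "dmtpv", mustWork = TRUE)
  yaml::read_yaml(path)
}

assert_in <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

## Percentage on a fixed denominator, rounded half-up to 1 decimal as in the
## published tables; returns 0 for a zero denominator.
pct <- function(n, denom, digits = 1) {
  d <- rep_len(as.numeric(denom), length(n))
  out <- numeric(length(n))
  ok <- d > 0
  out[ok] <- round_half_up(100 * n[ok] / d[ok], digits)
  out
}

## seriousness field is a ";"-joined token string; an event is serious when
## it carries any criterion other than "none".
split_criteria <- function(s) {
  out <- strsplit(as.character(s), ";", fixed = TRUE)
  lapply(out, function(x) {
    x <- norm_ws(x)
    x[nzchar(x)]
  })
}

is_serious_event <- function(s) {
  vapply(split_criteria(s), function(x) any(x != "none"), logical(1))
}
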