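#!/usr/bin/env Rscript

## Stage 2 — select the pregnancy/lactation cases.
##
## Reads the per-drug exports written by stage 1, merges them, applies the
## keyword/route inclusion rules and the two exclusions, classifies each
## selected case's exposure type, and writes the audit trail.

suppressPackageStartupMessages(library(dmtpv))

data_dir <- file.path("results", "data")
exports <- lapply(dmt_drugs(), function(d) {
  read_line_listing(file.path(data_dir, sprintf("exact_%s.csv", d)))
})
merged <- merge_drug_exports(exports)
cat(sprintf("retrieved %d cases across %d exports\n", n_cases(merged),
            length(exports)))

sel <- select_cases(merged)
write.csv(sel$audit, file.path("results", "selection_audit.csv"),
          row.names = FALSE)
write.csv(sel$case_log, file.path("results", "selection_case_log.csv"),
          row.names = FALSE)
write_line_listing(sel$selected, file.path("results", "selected_cases.csv"),
                   format = "long")

print(sel$audit)
cls <- table(sel$selected$cases$exposure_class)
cat("exposure classes of the selected cases:\n")
print(cls)
cat(sprintf("selected %d of %d cases; every retrieved case reconciled\n",
            n_cases(sel$selected), n_cases(merged)))
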