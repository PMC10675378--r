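#!/usr/bin/env Rscript

## Stage 1 — assemble the analysis case set.
##
## Writes per-drug line listings for (a) the exact-count case set, whose
## marginals equal the published tables cell for cell, and (b) one
## stochastic replicate drawn under the same study conditions. Later stages
## read these files, so the whole workflow exercises the same ingest path a
## real export download would.

suppressPackageStartupMessages(library(dmtpv))

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- fixture_exact_counts()
for (d in dmt_drugs()) {
  keys <- dmtpv:::case_key(fx$cases$cases)
  sub <- dmtpv:::subset_cases(fx$cases, keys[fx$cases$cases$drug_group == d])
  write_line_listing(sub, file.path(out, sprintf("exact_%s.csv", d)))
  cat(sprintf("exact-count export %-12s %4d cases %5d events\n", d,
              n_cases(sub), n_events(sub)))
}

sim <- generate_cases(default_config(seed = 20230306))
write_line_listing(sim$cases, file.path(out, "simulated_replicate.csv"),
                   format = "long")
cat(sprintf("simulated replicate       %4d cases %5d events (seed 20230306)\n",
            n_cases(sim$cases), n_events(sim$cases)))
cat(sprintf("exact-count total         %4d cases %5d events, %.1f events/case\n",
            n_cases(fx$cases), n_events(fx$cases),
            mean_events_per_case(fx$cases)))
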