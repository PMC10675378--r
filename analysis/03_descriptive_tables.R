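#!/usr/bin/env Rscript

## Stage 3 — descriptive tables.
##
## Case characteristics, event-group distribution with the four
## most-reported terms per group, and the seriousness/outcome distribution
## of the events.

suppressPackageStartupMessages(library(dmtpv))

exports <- lapply(dmt_drugs(), function(d) {
  read_line_listing(file.path("results", "data",
                              sprintf("exact_%s.csv", d)))
})
sel <- select_cases(merge_drug_exports(exports))

ch <- tabulate_characteristics(sel$selected)
write.csv(ch, file.path("results", "table1_characteristics.csv"),
          row.names = FALSE)

asg <- assign_groups(sel$selected)
cnt <- group_counts(asg)
write.csv(cnt$groups, file.path("results", "table2_group_counts.csv"),
          row.names = FALSE)
top <- top_pts_per_group(cnt, k = 4)
write.csv(top, file.path("results", "table2_top_pts.csv"),
          row.names = FALSE)

so <- tabulate_seriousness_outcome(sel$selected)
write.csv(so, file.path("results", "table3_seriousness_outcome.csv"),
          row.names = FALSE)

cat(sprintf("events per case: %.1f\n", mean_events_per_case(sel$selected)))
ser <- ch[ch$block == "seriousness" & ch$level == "serious", ]
cat(sprintf("serious cases: %d (%.1f%%)\n", ser$total, ser$total_pct))
ns <- so[so$block == "seriousness" & so$level == "none", ]
cat(sprintf("serious events: %d of %d (%.1f%%)\n", sum(cnt$groups$total) -
              ns$total, sum(cnt$groups$total),
            100 - ns$total_pct))
cat("event-group totals:\n")
print(cnt$groups[, c("group", "total")])
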