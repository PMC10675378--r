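test_that("case characteristics reproduce the published totals", {
  ch <- tabulate_characteristics(exact_selected()$selected)
  row <- function(block, level) ch[ch$block == block & ch$level == level, ]
  hp <- row("reporter", "healthcare_professional")
  expect_equal(hp$total, 1051)
  expect_equal(hp$total_pct, 85.0)
  ser <- row("seriousness", "serious")
  expect_equal(ser$total, 986)
  expect_equal(ser$total_pct, 79.8)
  expect_equal(row("age", "neonate_0_1m")$total, 135)
  expect_equal(row("age", "18_64")$total_pct, 58.2)
  expect_equal(row("baby_sex", "male")$total, 69)
  expect_equal(row("report_type", "spontaneous")$glatiramer_pct, 100.0)
  expect_equal(row("exposure", "during_pregnancy_or_transplacental")$total,
               1048)
  expect_equal(row("suspect_other", "0")$total, 921)
  expect_equal(row("concomitant", "not_reported")$total, 1013)
})

test_that("each characteristics block sums to its case denominator", {
  sel <- exact_selected()$selected
  ch <- tabulate_characteristics(sel)
  n_drug <- table(factor(sel$cases$drug_group,
                         levels = published_drug_order()))
  for (b in setdiff(unique(ch$block), "baby_sex")) {
    blk <- ch[ch$block == b, ]
    expect_equal(colSums(blk[, published_drug_order()]),
                 as.vector(n_drug), ignore_attr = TRUE, label = b)
  }
  ## baby sex is tabulated over the cases involving a child
  bs <- ch[ch$block == "baby_sex", ]
  expect_equal(sum(bs$total), sum(sel$cases$child_age_group != "none"))
})

test_that("published percentages recompute from their own counts", {
  ch <- tabulate_characteristics(exact_selected()$selected)
  n_total <- 1236
  expect_true(all(abs(ch$total_pct - 100 * ch$total / n_total) <= 0.05 +
                    1e-9))
  so <- tabulate_seriousness_outcome(exact_selected()$selected)
  expect_true(all(abs(so$total_pct - 100 * so$total / 3590) <= 0.05 + 1e-9))
})

test_that("seriousness and outcome distributions match the published event table", {
  so <- tabulate_seriousness_outcome(exact_selected()$selected)
  row <- function(block, level) so[so$block == block & so$level == level, ]
  expect_equal(row("seriousness", "none")$total, 952)
  expect_equal(row("seriousness", "none")$total_pct, 26.5)
  expect_equal(row("seriousness", "other_medically_important")$total, 1738)
  expect_equal(row("seriousness", "death")$natalizumab, 67)
  expect_equal(row("seriousness", "disabling")$glatiramer, 4)
  expect_equal(sum(so[so$block == "seriousness", "total"]) -
                 row("seriousness", "none")$total, 2638)
  un <- row("outcome", "unknown")
  expect_equal(un$total, 1724)
  expect_equal(un$total_pct, 48.0)
  expect_equal(un$glatiramer_pct, 75.3)
  expect_equal(row("outcome", "fatal")$total,
               row("seriousness", "death")$total)
  ## outcome block is a partition of the events
  out_blk <- so[so$block == "outcome", ]
  expect_equal(colSums(out_blk[, published_drug_order()]),
               c(720, 666, 1943, 261), ignore_attr = TRUE)
})

test_that("mean events per case matches the published scalar and a naive recount", {
  expect_equal(mean_events_per_case(exact_selected()$selected), 2.9)
  one <- mini_set("glatiramer", lapply(1:4, function(i) {
    data.frame(pt = "Abortion spontaneous")
  }))
  expect_equal(mean_events_per_case(one), 1.0)
  g <- generate_cases(default_config(seed = 3))$cases
  naive <- nrow(g$events) / nrow(g$cases)
  expect_equal(mean_events_per_case(g, digits = 6),
               round_half_up(naive, 6))
  expect_error(mean_events_per_case(empty_icsr_set()), "empty")
})

test_that("top terms per group rank by total with alphabetical ties", {
  top <- top_pts_per_group(exact_group_counts(), k = 4)
  term1 <- top[top$group == "termination_abortion" & top$rank == 1, ]
  expect_equal(term1$pt, "Abortion spontaneous")
  expect_equal(term1$total, 321)
  neo1 <- top[top$group == "neonatal_disorders" & top$rank == 1, ]
  expect_equal(neo1$pt, "Premature baby")
  expect_equal(neo1$total, 62)
  ## equal counts break alphabetically
  mat <- top[top$group == "maternal_other", ]
  expect_equal(mat$pt, c("Multiple sclerosis relapse", "Haemorrhage",
                         "Anaemia", "Dyspnoea"))
  expect_equal(nrow(top_pts_per_group(exact_group_counts(), k = 0)), 0)
})

test_that("a single case tabulates to one 100 percent row per block", {
  x <- mini_set("ocrelizumab",
                list(data.frame(pt = c("Maternal exposure during pregnancy",
                                       "Abortion spontaneous"))))
  sel <- select_cases(x)$selected
  ch <- tabulate_characteristics(sel)
  pop <- ch[ch$ocrelizumab > 0, ]
  expect_true(all(pop$ocrelizumab_pct == 100))
})
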