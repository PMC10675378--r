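test_that("contingency tables are built from the group/term counts", {
  cnt <- exact_group_counts()
  t1 <- build_contingency(cnt$pts, "Abortion spontaneous", "natalizumab",
                          "glatiramer",
                          totals = c(natalizumab = 1943, glatiramer = 720))
  expect_equal(unname(unlist(t1[c("a", "b", "c", "d")])),
               c(235, 1708, 42, 678))
  t2 <- build_contingency(cnt$groups, "termination_abortion", "ocrelizumab",
                          "glatiramer")
  expect_equal(unname(unlist(t2[c("a", "b", "c", "d")])),
               c(38, 223, 55, 665))
  t0 <- build_contingency(cnt$groups, "foetal_other", "natalizumab",
                          "glatiramer")
  expect_equal(t0$a, 0)
  expect_equal(t0$a + t0$b, 1943)
  expect_error(build_contingency(cnt$groups, "no such group", "natalizumab",
                                 "glatiramer"), "unknown target")
  expect_error(build_contingency(cnt$groups, "foetal_other", "aspirin",
                                 "glatiramer"), "unknown drug")
})

test_that("the reporting odds ratio is ad/(bc), undefined on zero cells", {
  expect_equal(round_half_up(compute_ror(list(a = 235, b = 1708, c = 42,
                                              d = 678)), 2), 2.22)
  for (x in c(1, 7, 50)) {
    expect_equal(compute_ror(list(a = x, b = 11, c = x, d = 11)), 1.0)
  }
  expect_true(is.na(compute_ror(list(a = 0, b = 10, c = 5, d = 10))))
  expect_error(compute_ror(list(a = -1, b = 1, c = 1, d = 1)),
               "non-negative")
  ## exact integer-arithmetic oracle on random tables
  tabs <- random_tables(100, seed = 8)
  for (i in seq_len(nrow(tabs))) {
    t <- as.list(tabs[i, ])
    exact <- (t$a * t$d) / (t$b * t$c)  # products are exact in doubles here
    expect_equal(compute_ror(t), exact, tolerance = 1e-12)
  }
})

test_that("Woolf intervals reproduce the published bounds", {
  ci <- woolf_ci(list(a = 235, b = 1708, c = 42, d = 678))
  expect_equal(round_half_up(ci, 2), c(low = 1.58, high = 3.12))
  ci2 <- woolf_ci(list(a = 130, b = 1813, c = 18, d = 702))
  expect_equal(round_half_up(ci2, 2), c(low = 1.70, high = 4.61))
  bal <- woolf_ci(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(unname(bal["low"] * bal["high"]), 1, tolerance = 1e-12)
  expect_true(bal["low"] < 1 && bal["high"] > 1)
  expect_true(all(is.na(woolf_ci(list(a = 0, b = 1, c = 1, d = 1)))))
  expect_error(woolf_ci(list(a = 1, b = 1, c = 1, d = 1), alpha = 0),
               "alpha")
})

test_that("antisymmetry and margin invariance hold against the exact oracle", {
  tabs <- random_tables(250, seed = 12)
  for (i in seq_len(nrow(tabs))) {
    t <- as.list(tabs[i, ])
    swapped <- list(a = t$c, b = t$d, c = t$a, d = t$b)
    expect_equal(compute_ror(swapped), 1 / compute_ror(t),
                 tolerance = 1e-12)
    ci <- woolf_ci(t)
    ci_sw <- woolf_ci(swapped)
    expect_equal(unname(ci_sw), unname(rev(1 / ci)), tolerance = 1e-12)
    k <- sample(2:5, 1)
    scaled <- list(a = t$a * k, b = t$b * k, c = t$c, d = t$d)
    expect_equal(compute_ror(scaled), compute_ror(t), tolerance = 1e-12)
  }
})

test_that("the interval always contains the estimate and narrows with information", {
  tabs <- random_tables(50, seed = 21)
  for (i in seq_len(nrow(tabs))) {
    t <- as.list(tabs[i, ])
    r <- compute_ror(t)
    ci <- woolf_ci(t)
    expect_true(ci["low"] <= r && r <= ci["high"])
    big <- lapply(t, `*`, 4L)
    ci_big <- woolf_ci(big)
    expect_true(log(ci_big["high"] / ci_big["low"]) <
                  log(ci["high"] / ci["low"]))
  }
})

test_that("term eligibility needs >= 3 reporting cases for every drug", {
  asg <- exact_assignments()
  expect_equal(eligible_pts(asg),
               c("Abortion spontaneous", "Multiple sclerosis relapse"))
  ## brute-force scan oracle on the same data
  adr <- asg[asg$group != "not_indicating_adr", ]
  brute <- sort(Filter(function(p) {
    all(vapply(dmt_drugs(), function(d) {
      length(unique(adr$case_id[adr$pt == p & adr$drug_group == d])) >= 3
    }, logical(1)))
  }, unique(adr$pt)))
  expect_equal(eligible_pts(asg), brute)
  ## all counts below threshold -> nothing eligible
  small <- asg[asg$pt == "Foetal death", ]
  expect_equal(eligible_pts(small), character())
  ## exposure coding never qualifies, however frequent
  expect_false("Maternal exposure during pregnancy" %in% eligible_pts(asg))
})

test_that("the full analysis reproduces the published estimates", {
  res <- run_disproportionality(exact_assignments())
  pick <- function(target, drug) {
    r <- res[res$target == target & res$drug == drug, ]
    c(round_half_up(r$ror, 2), round_half_up(r$ci_low, 2),
      round_half_up(r$ci_high, 2))
  }
  expect_equal(pick("Multiple sclerosis relapse", "alemtuzumab"),
               c(0.17, 0.07, 0.45))
  expect_equal(pick("termination_abortion", "alemtuzumab")[1], 0.37)
  expect_equal(pick("Abortion spontaneous", "ocrelizumab"),
               c(2.18, 1.34, 3.54))
  ## zero-cell group results are flagged, not dropped
  und <- res[res$target == "foetal_other" & res$drug == "natalizumab", ]
  expect_false(und$defined)
  expect_true(is.na(und$ror))
  expect_equal(nrow(res), 3 * (9 + 2))
  ## significance means the interval excludes 1
  ok <- res$defined
  expect_equal(res$significant[ok],
               res$ci_low[ok] > 1 | res$ci_high[ok] < 1)
})

test_that("a missing comparator is a configuration error", {
  asg <- exact_assignments()
  only_nat <- asg[asg$drug_group == "natalizumab", ]
  expect_error(run_disproportionality(only_nat), "comparator|drug of interest")
  only_gla <- asg[asg$drug_group == "glatiramer", ]
  expect_error(run_disproportionality(only_gla), "no drug of interest")
})
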