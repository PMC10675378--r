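test_that("inclusion matches exposure terms, word list and routes", {
  r1 <- match_inclusion("Maternal exposure during pregnancy")
  expect_true(r1$match)
  expect_true("maternal exposure during pregnancy" %in% r1$matched_terms ||
                "maternal" %in% r1$matched_terms)

  r2 <- match_inclusion("Headache", routes = "Transplacental")
  expect_true(r2$match)
  expect_equal(r2$matched_terms, "Transplacental")

  r3 <- match_inclusion("Headache")
  expect_false(r3$match)
  expect_length(r3$matched_terms, 0)

  ## every published retrieval word is honoured
  for (w in c("foetal", "premature", "milk", "breastfeeding", "neonatal",
              "baby", "abortion", "still birth", "malformation",
              "congenital")) {
    expect_true(match_inclusion(paste("Some", w, "term"))$match, label = w)
  }
})

test_that("exclusions: paternal exposure always, adult-age conflicts only without other evidence", {
  expect_equal(apply_exclusions("Paternal drug exposure"),
               list(keep = FALSE, reason = "paternal_exposure"))
  expect_true(apply_exclusions("Abortion spontaneous")$keep)
  r <- apply_exclusions("Premature menopause")
  expect_false(r$keep)
  expect_equal(r$reason, "adult_age_conflict")
  ## exposure coding or a route rescues the case
  expect_true(apply_exclusions(c("Premature menopause",
                                 "Maternal exposure during pregnancy"))$keep)
  expect_true(apply_exclusions("Premature menopause",
                               routes = "Transplacental")$keep)
  expect_true(apply_exclusions(c("Premature menopause",
                                 "Abortion spontaneous"))$keep)
})

test_that("exposure classification follows the published priority order", {
  expect_equal(classify_exposure("Exposure via breast milk"),
               "breastfeeding_or_transmammary")
  expect_equal(classify_exposure("Maternal exposure before pregnancy"),
               "before_pregnancy")
  expect_equal(classify_exposure("Abortion spontaneous"), "not_specified")
  expect_equal(classify_exposure(c("Exposure via breast milk",
                                   "Maternal exposure during pregnancy")),
               "during_pregnancy_or_transplacental")
  expect_equal(classify_exposure("Headache", routes = "Transmammary"),
               "breastfeeding_or_transmammary")
  expect_equal(classify_exposure("Headache", routes = "Transplacental"),
               "during_pregnancy_or_transplacental")
})

test_that("a constructed set selects and audits as planted", {
  x <- mini_set("natalizumab", c(
    lapply(1:6, function(i) data.frame(pt = c(
      "Maternal exposure during pregnancy", "Abortion spontaneous"))),
    list(data.frame(pt = c("Paternal drug exposure", "Congenital anomaly"))),
    lapply(1:3, function(i) data.frame(pt = "Headache"))))
  out <- select_cases(x)
  expect_equal(n_cases(out$selected), 6)
  expect_equal(out$audit$retrieved, 10)
  expect_equal(out$audit$excluded_inclusion_miss, 3)
  expect_equal(out$audit$excluded_paternal_exposure, 1)
  expect_equal(out$audit$excluded_adult_age_conflict, 0)
  expect_true(all(out$selected$cases$exposure_class ==
                    "during_pregnancy_or_transplacental"))

  empty <- select_cases(empty_icsr_set())
  expect_equal(n_cases(empty$selected), 0)
  expect_equal(nrow(empty$audit), 0)
})

test_that("the exact-count case set selects in full at the published sizes", {
  out <- exact_selected()
  expect_equal(n_cases(out$selected), 1236)
  expect_equal(out$audit$included[match(published_drug_order(),
                                        out$audit$drug_group)],
               c(201, 100, 839, 96))
  expect_equal(sum(out$audit$retrieved - out$audit$included), 0)
})

test_that("selection is idempotent and exposure classes partition the selected set", {
  cfg <- default_config(seed = 5)
  cfg$paternal_fraction <- 0.05
  cfg$inclusion_miss_fraction <- 0.05
  cfg$adult_conflict_fraction <- 0.02
  g <- generate_cases(cfg)
  s1 <- select_cases(g$cases)
  s2 <- select_cases(s1$selected)
  expect_equal(s2$selected$cases, s1$selected$cases)
  expect_equal(n_cases(s2$selected), n_cases(s1$selected))

  cls <- s1$selected$cases$exposure_class
  expect_false(any(is.na(cls)))
  expect_true(all(cls %in% dmtpv:::exposure_class_levels()))
  expect_equal(sum(table(cls)), n_cases(s1$selected))
})

test_that("selection reproduces generator truth labels exactly", {
  cfg <- default_config(seed = 31)
  cfg$paternal_fraction <- 0.06
  cfg$inclusion_miss_fraction <- 0.08
  cfg$adult_conflict_fraction <- 0.03
  g <- generate_cases(cfg)
  out <- select_cases(g$cases)
  lab <- g$case_labels
  log <- out$case_log
  m <- merge(log, lab, by = c("drug_group", "case_id"))
  expect_equal(nrow(m), nrow(lab))
  expect_equal(m$status == "included", m$include)
  excl <- m[!m$include, ]
  expect_equal(excl$status,
               ifelse(excl$reason == "inclusion_miss", "inclusion_miss",
                      excl$reason))
  ## exposure classes agree on included cases
  sel <- out$selected$cases
  m2 <- merge(sel, lab, by = c("drug_group", "case_id"))
  expect_equal(m2$exposure_class.x, m2$exposure_class.y)
})
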