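test_that("packed reaction cells parse to the expected events", {
  ev <- parse_reaction_list(
    "Abortion spontaneous (– Unknown – Other Medically Important Condition)")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pt, "Abortion spontaneous")
  expect_equal(ev$outcome, "unknown")
  expect_equal(ev$seriousness, "other_medically_important")
  expect_equal(ev$subject, "unspecified")

  expect_equal(nrow(parse_reaction_list("")), 0)
  expect_equal(nrow(parse_reaction_list(NA)), 0)

  multi <- parse_reaction_list(paste0(
    "Caesarean section (– Recovered/Resolved – Caused/Prolonged Hospitalisation), ",
    "Premature baby (3d – Fatal – Results in Death; Congenital Anomaly)"))
  expect_equal(multi$pt, c("Caesarean section", "Premature baby"))
  expect_equal(multi$duration, c("", "3d"))
  expect_equal(split_criteria(multi$seriousness[2])[[1]],
               c("death", "congenital_anomaly"))
})

test_that("malformed packing is an error naming the fragment; unknown labels degrade", {
  expect_error(parse_reaction_list("no parenthesis block"),
               "malformed reaction fragment.*no parenthesis block")
  expect_error(parse_reaction_list("Headache (only one field)"),
               "malformed reaction detail")
  expect_warning(
    ev <- parse_reaction_list("Headache (– Something Odd – Not Serious)"),
    "unrecognised outcome")
  expect_equal(ev$outcome, "unknown")
  expect_warning(
    ev2 <- parse_reaction_list("Headache (– Unknown – Mystery Criterion)"),
    "unrecognised seriousness")
  expect_equal(ev2$seriousness, "none")
})

test_that("pack then parse is the identity on event tables", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    ev <- data.frame(
      pt = paste("Term", sample(100, k)),
      duration = sample(c("", "2d", "1w"), k, replace = TRUE),
      outcome = sample(dmtpv:::outcome_levels(), k, replace = TRUE),
      seriousness = sample(dmtpv:::seriousness_levels(), k, replace = TRUE),
      subject = "unspecified", stringsAsFactors = FALSE)
    back <- parse_reaction_list(pack_reaction_list(ev))
    expect_equal(back, ev, ignore_attr = TRUE)
    expect_equal(nrow(back), k)  # no event silently dropped
  }
})

test_that("write then read round-trips both dialect formats", {
  x <- generate_cases(default_config(seed = 11))$cases
  x <- dmtpv:::subset_cases(x, dmtpv:::case_key(x$cases)[1:120])
  for (fmt in c("packed", "long")) {
    p <- withr::local_tempfile(fileext = ".csv")
    write_line_listing(x, p, format = fmt)
    y <- read_line_listing(p)
    expect_equal(y$cases, x$cases)
    expect_equal(y$events, x$events)
    expect_equal(y$drugs, x$drugs)
  }
})

test_that("schema and duplicate-id problems are reported", {
  p <- withr::local_tempfile(fileext = ".csv")
  x <- mini_set("natalizumab", list(data.frame(pt = "Abortion spontaneous")))
  write_line_listing(x, p)
  raw <- read.csv(p, check.names = FALSE, colClasses = "character")
  raw[["Reaction List PT"]] <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, p2, row.names = FALSE)
  expect_error(read_line_listing(p2), "missing column")

  dup <- rbind(raw0 <- read.csv(p, check.names = FALSE,
                                colClasses = "character"), raw0)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, p3, row.names = FALSE)
  expect_error(read_line_listing(p3), "duplicate case id.*C001")

  expect_error(read_line_listing(withr::local_tempfile()), "no such file")
})

test_that("merging per-drug exports keeps per-drug semantics", {
  fx <- exact_fixture()$cases
  per_drug <- lapply(dmt_drugs(), function(d) {
    dmtpv:::subset_cases(fx, dmtpv:::case_key(fx$cases)[
      fx$cases$drug_group == d])
  })
  merged <- merge_drug_exports(per_drug)
  expect_equal(n_cases(merged), 1236)
  expect_equal(as.vector(table(factor(merged$cases$drug_group,
                                      levels = published_drug_order()))),
               c(201, 100, 839, 96))

  expect_equal(n_cases(merge_drug_exports(list())), 0)

  a <- mini_set("natalizumab", list(data.frame(pt = "Abortion spontaneous")))
  b <- mini_set("glatiramer", list(data.frame(pt = "Abortion spontaneous")))
  both <- merge_drug_exports(list(a, b))  # same case_id, two drug groups
  expect_equal(n_cases(both), 2)
})

test_that("case-level seriousness is the disjunction of event seriousness", {
  fx <- exact_fixture()$cases
  serious <- dmtpv:::case_serious(fx)
  ev_ser <- tapply(dmtpv:::is_serious_event(fx$events$seriousness),
                   dmtpv:::case_key(fx$events), any)
  expect_equal(unname(serious),
               unname(as.logical(ev_ser[dmtpv:::case_key(fx$cases)])))
})

test_that("construction invariants are enforced", {
  x <- mini_set("natalizumab", list(data.frame(pt = "Headache")))
  bad <- x
  bad$events <- bad$events[0, ]
  expect_error(validate_icsr_set(bad), "no reaction events")
  bad2 <- x
  bad2$drugs$name <- "aspirin"
  expect_error(validate_icsr_set(bad2), "suspect mention")
  bad3 <- x
  bad3$events$outcome <- "vanished"
  expect_error(validate_icsr_set(bad3), "invalid outcome")
  warned <- x
  warned$events$outcome <- "fatal"
  warned$events$seriousness <- "other_medically_important"
  expect_warning(validate_icsr_set(warned), "fatal event")
})
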