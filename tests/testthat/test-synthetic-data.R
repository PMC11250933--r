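test_that("generate_corpus is deterministic, sized and balanced", {
  c1 <- generate_corpus("BI", n = 100, seed = 1)
  c2 <- generate_corpus("BI", n = 100, seed = 1)
  expect_identical(c1, c2)
  expect_equal(nrow(generate_corpus("BI", n = 0)), 0)
  big <- generate_corpus("BI", n = 1000, seed = 2)
  frac <- mean(big$label == "positive")
  expect_gte(frac, 0.375); expect_lte(frac, 0.415)
  hf <- generate_corpus("HFFO_radiology", n = 1000, seed = 3)
  expect_equal(mean(hf$label == "positive"), 0.564, tolerance = 0.002)
  echo <- generate_corpus("HFFO_echo", n = 1000, seed = 4)
  expect_equal(mean(echo$label == "positive"), 0.501, tolerance = 0.002)
  expect_true(all(echo$source_category == "echo"))
})

test_that("BI labels are consistent with a keyword oracle at zero noise", {
  corpus <- generate_corpus("BI", n = 600, seed = 11, noise_rate = 0)
  marker <- "(?i)(bilateral|both lung|right and left)"
  blocker <- "(?i)(resolution|effusion|atelectasis|clear|no evidence|without)"
  says_bilateral <- grepl(marker, corpus$text, perl = TRUE) &
    !grepl(blocker, corpus$text, perl = TRUE)
  pos <- corpus$label == "positive"
  expect_gte(mean(says_bilateral[pos]), 0.99)
  expect_equal(mean(says_bilateral[!pos]), 0)
})

test_that("HF/FO units always contain a trigger keyword", {
  for (task in c("HFFO_radiology", "HFFO_echo")) {
    corpus <- generate_corpus(task, n = 200, seed = 13)
    n_docs <- vapply(corpus$text,
                     function(t) nrow(extract_hffo_documents(t)), integer(1))
    expect_true(all(n_docs >= 1), info = task)
  }
})

test_that("generate_cohort is deterministic and handles n = 0", {
  g1 <- generate_cohort(generator_config(n = 15, seed = 8))
  g2 <- generate_cohort(generator_config(n = 15, seed = 8))
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$evidence, g2$evidence)
  expect_equal(verdicts_to_df(detect_cohort(g1$admissions,
                                            evidence = g1$evidence)),
               verdicts_to_df(detect_cohort(g2$admissions,
                                            evidence = g2$evidence)))
  empty <- generate_cohort(generator_config(n = 0))
  expect_length(empty$admissions, 0)
})

test_that("every scenario reproduces its expected verdict under the engine", {
  co <- generate_cohort(generator_config(n = 240, seed = 101))
  expect_setequal(unique(co$labels$scenario), c(
    "classic_ards", "hffo_confounded", "rapid_resolution", "early_trach",
    "short_vent_survivor", "short_vent_expired", "no_hypoxemia",
    "unilateral_disease"))
  verdicts <- verdicts_to_df(detect_cohort(co$admissions,
                                           evidence = co$evidence))
  m <- merge(verdicts, co$labels, by = "admission_id")
  expect_equal(m$ards, m$expected_flag)
  neg <- m[!m$expected_flag, ]
  expect_equal(neg$failed_reason, neg$expected_reason)
  pos <- m[m$expected_flag, ]
  expect_equal(pos$onset_time, pos$expected_onset)
  expect_equal(pos$severity, pos$expected_severity)
})

test_that("clinical labels depart from engine expectations only where documented", {
  co <- generate_cohort(generator_config(n = 300, seed = 55))
  lab <- co$labels
  mismatch <- lab[lab$ards_label != lab$expected_flag, ]
  expect_true(all(mismatch$scenario %in% c("unilateral_disease",
                                           "hffo_confounded")))
  expect_true(all(mismatch$flavor[mismatch$scenario == "hffo_confounded"] ==
                    "masked"))
  # the cohort passes its own filter (all scenarios produce analyzable data)
  expect_length(cohort_filter(co$admissions)$admissions,
                length(co$admissions))
})
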