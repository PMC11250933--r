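bi_config <- text_pipeline_config(split_ratio = 0.75)

test_that("training on a separable synthetic corpus yields high held-out F1", {
  corpus <- generate_corpus("BI", n = 200, seed = 7)
  fit <- train_text_classifier(corpus, task = "BI", config = bi_config,
                               seed = 7)
  expect_s3_class(fit, "trained_text_classifier")
  expect_gte(fit$holdout[["f1_pos"]], 0.95)
  expect_equal(fit$metadata$n_train + fit$metadata$n_test, 200)
  expect_equal(fit$metadata$n_train, 150)   # 75:25 stratified split
})

test_that("training rejects single-class data and undersized corpora", {
  corpus <- generate_corpus("BI", n = 120, seed = 8)
  allpos <- corpus[corpus$label == "positive", ]
  expect_error(train_text_classifier(allpos, config = bi_config),
               "single class")
  expect_error(train_text_classifier(corpus[1:20, ], config = bi_config),
               "too few")
})

test_that("training is deterministic for a fixed seed", {
  corpus <- generate_corpus("BI", n = 150, seed = 12)
  probes <- generate_corpus("BI", n = 60, seed = 99)$text
  f1 <- train_text_classifier(corpus, config = bi_config, seed = 4)
  f2 <- train_text_classifier(corpus, config = bi_config, seed = 4)
  expect_identical(classify_texts(f1, probes)$label,
                   classify_texts(f2, probes)$label)
  expect_equal(classify_texts(f1, probes)$score,
               classify_texts(f2, probes)$score)
})

test_that("serialization round trip preserves predictions", {
  corpus <- generate_corpus("HFFO_echo", n = 200, seed = 5, noise_rate = 0.1)
  fit <- train_text_classifier(corpus, task = "HFFO_echo",
                               config = text_pipeline_config(split_ratio = 0.8),
                               seed = 5)
  probes <- generate_corpus("HFFO_echo", n = 100, seed = 123)$text
  before <- classify_texts(fit, probes)
  path <- tempfile(fileext = ".json")
  save_text_classifier(fit, path)
  back <- load_text_classifier(path)
  after <- classify_texts(back, probes)
  expect_identical(before$label, after$label)
  expect_equal(before$score, after$score)
  expect_equal(back$task, "HFFO_echo")
})

test_that("classify_report implements the any-positive-sentence rule", {
  corpus <- generate_corpus("BI", n = 200, seed = 7)
  fit <- train_text_classifier(corpus, config = bi_config, seed = 7)
  report <- paste("The lungs are clear without pneumonia.",
                  "Tubes are unchanged.",
                  "Bilateral infiltrates are again demonstrated.",
                  "No evidence of aspiration.")
  note <- list(category = "chest_radiograph", text = report)
  res <- classify_report(note, fit)
  # brute-force equivalence: report label == any() over sentence labels
  sent_labels <- classify_texts(fit, split_sentences(report))$label
  expect_equal(res$label == "positive", any(sent_labels == "positive"))
  expect_equal(nrow(res$unit_decisions), 4)
  # an all-negative report comes out negative
  neg <- classify_report(list(category = "chest_radiograph",
                              text = "The lungs are clear. No effusion."),
                         fit)
  expect_equal(neg$label, "negative")
  # empty report: negative with no units
  empty <- classify_report(list(category = "chest_radiograph", text = ""), fit)
  expect_equal(empty$label, "negative")
  expect_equal(nrow(empty$unit_decisions), 0)
  # task/category mismatch is an error
  expect_error(classify_report(list(category = "echo", text = "x"), fit),
               "cannot classify")
})

test_that("HF/FO reports without trigger keywords are negative by extraction", {
  corpus <- generate_corpus("HFFO_radiology", n = 200, seed = 6)
  fit <- train_text_classifier(corpus, task = "HFFO_radiology",
                               config = text_pipeline_config(split_ratio = 0.8),
                               seed = 6)
  res <- classify_report(list(category = "chest_radiograph",
                              text = "The lungs are clear. Tubes unchanged."),
                         fit)
  expect_equal(res$label, "negative")
  expect_equal(nrow(res$unit_decisions), 0)
})

test_that("replicate_evaluation summarizes across seeds and validates n_reps", {
  corpus <- generate_corpus("BI", n = 150, seed = 31)
  expect_error(replicate_evaluation(corpus, n_reps = 1, base_seed = 1),
               "n_reps")
  res <- replicate_evaluation(corpus, config = bi_config, n_reps = 2,
                              base_seed = 41)
  expect_equal(nrow(res$replicates), 2)
  expect_true(all(c("min", "max", "mean", "ci95_halfwidth") %in%
                    names(res$summary)))
  expect_true(all(is.finite(res$summary$ci95_halfwidth)))
  acc <- res$summary[res$summary$metric == "accuracy", ]
  expect_gte(acc$min, 0.9)   # separable templates
})
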