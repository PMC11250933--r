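test_that("compute_metrics agrees with direct arithmetic on random matrices", {
  set.seed(19)
  for (i in 1:2000) {
    cm <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = sample(0:50, 1))
    total <- cm$tp + cm$fp + cm$fn + cm$tn
    if (total == 0) next
    m <- compute_metrics(cm)
    expect_equal(m$accuracy, 100 * (cm$tp + cm$tn) / total)
    if (cm$tn + cm$fp > 0) {
      expect_equal(m$specificity, 100 * cm$tn / (cm$tn + cm$fp))
    }
    if (cm$tp + cm$fn > 0) {
      expect_equal(m$recall, 100 * cm$tp / (cm$tp + cm$fn))
    }
    if (cm$tp + cm$fp > 0) {
      expect_equal(m$precision, 100 * cm$tp / (cm$tp + cm$fp))
    }
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
    }
  }
})

test_that("compute_metrics handles perfect and degenerate matrices", {
  perfect <- compute_metrics(list(tp = 10, fp = 0, fn = 0, tn = 20))
  expect_equal(c(perfect$accuracy, perfect$specificity, perfect$recall,
                 perfect$precision, perfect$f1), rep(100, 5))
  deg <- compute_metrics(list(tp = 0, fp = 0, fn = 5, tn = 10))
  expect_equal(deg$precision, 0)
  expect_equal(deg$recall, 0)
  expect_true(all(c("precision", "f1") %in% deg$undefined))
  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "all zero")
})

test_that("confusion_matrix counts each cell", {
  cm <- confusion_matrix(pred = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                         truth = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(cm, list(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
})

small_cohort <- function(n = 40, seed = 29) {
  co <- generate_cohort(generator_config(n = n, seed = seed))
  list(adm = co$admissions,
       labels = data.frame(admission_id = co$labels$admission_id,
                           ards_label = co$labels$ards_label),
       evidence = co$evidence, raw = co)
}

test_that("tune_windows evaluates the full grid and a singleton grid", {
  sc <- small_cohort()
  tuned <- tune_windows(sc$adm, sc$labels, sc$evidence,
                        candidates = c(1440, 7200))
  expect_equal(tuned$n_pairs, 4)
  single <- tune_windows(sc$adm, sc$labels, sc$evidence, candidates = 1440)
  expect_equal(single$n_pairs, 1)
  expect_equal(single$best_delta_bi, 1440)
  expect_equal(single$best_delta_hffo, 1440)
  # the selected pair attains the grid maximum (exhaustive recheck)
  best_f1 <- tuned$grid$f1[tuned$grid$delta_bi == tuned$best_delta_bi &
                             tuned$grid$delta_hffo == tuned$best_delta_hffo]
  expect_true(all(best_f1 >= tuned$grid$f1))
})

test_that("tune_windows rejects single-class labels", {
  sc <- small_cohort()
  sc$labels$ards_label <- TRUE
  expect_error(tune_windows(sc$adm, sc$labels, sc$evidence,
                            candidates = 1440), "single class")
})

test_that("ablation_run validates variants and reports baseline-only", {
  sc <- small_cohort()
  expect_error(ablation_run(sc$adm, sc$labels, sc$evidence,
                            variants = "no_such_thing"), "unknown variant")
  base <- ablation_run(sc$adm, sc$labels, sc$evidence)
  expect_equal(nrow(base), 1)
  expect_equal(base$variant, "baseline")
  expect_equal(base$delta_f1, 0)
})

test_that("oracle BI evidence dominates noisy BI evidence", {
  co <- generate_cohort(generator_config(
    n = 120, seed = 37,
    scenario_mix = c(classic_ards = 0.5, rapid_resolution = 0.25,
                     no_hypoxemia = 0.25)))
  labels <- data.frame(admission_id = co$labels$admission_id,
                       ards_label = co$labels$ards_label)
  noisy <- co$evidence
  set.seed(41)
  flip <- which(noisy$kind %in% c("bi_pos", "bi_neg") & runif(nrow(noisy)) < 0.2)
  noisy$kind[flip] <- ifelse(noisy$kind[flip] == "bi_pos", "bi_neg", "bi_pos")
  res <- ablation_run(co$admissions, labels, co$evidence,
                      variants = "oracle_bi", noisy_evidence = noisy)
  oracle <- res[res$variant == "oracle_bi", ]
  expect_gte(oracle$delta_accuracy, 0)
  expect_gte(oracle$delta_recall, 0)
  expect_gte(oracle$delta_f1, 0)
})

test_that("overlap_counts tallies method combinations", {
  flags <- data.frame(a = c(TRUE, TRUE, FALSE, FALSE),
                      b = c(TRUE, FALSE, FALSE, FALSE))
  oc <- overlap_counts(flags)
  expect_equal(oc$n[oc$combination == "a+b"], 1L)
  expect_equal(oc$n[oc$combination == "a"], 1L)
  expect_equal(oc$n[oc$combination == "(none)"], 2L)
})
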