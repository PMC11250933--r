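cfg <- berlin_config()

test_that("pf_series pairs PaO2 with recent FiO2 and carries PEEP forward", {
  a <- mk_admission(observations = obs_df(
    list(h(9), "peep", 8),
    list(h(9) + 30, "fio2", 0.4),
    list(h(10), "pao2", 60),
    list(h(20), "pao2", 70)))           # no FiO2 within 4 h -> skipped
  pf <- pf_series(a, cfg)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$pf_ratio, 150)
  expect_equal(pf$peep_at_time, 8)
  expect_equal(attr(pf, "n_unpaired"), 1L)
  # stale PEEP (> 8 h old) is absent
  b <- mk_admission(observations = obs_df(
    list(h(1), "peep", 8),
    list(h(10) - 30, "fio2", 0.4),
    list(h(10), "pao2", 60)))
  expect_true(is.na(pf_series(b, cfg)$peep_at_time))
  # no PaO2 -> empty series
  c0 <- mk_admission(observations = obs_df(list(h(1), "fio2", 0.4),
                                           list(h(1), "peep", 5)))
  expect_equal(nrow(pf_series(c0, cfg)), 0)
})

test_that("pf_series agrees with an exhaustive pairing scan on random series", {
  set.seed(77)
  for (i in 1:20) {
    times <- sort(sample(0:d(10), 30))
    obs <- data.frame(
      time = times,
      variable = sample(c("pao2", "fio2", "peep"), 30, replace = TRUE),
      value = 0, stringsAsFactors = FALSE)
    obs$value <- ifelse(obs$variable == "pao2", runif(30, 40, 120),
                 ifelse(obs$variable == "fio2",
                        sample(c(0.21, 0.4, 0.6, 1.0), 30, replace = TRUE),
                        sample(0:15, 30, replace = TRUE)))
    a <- mk_admission(observations = obs)
    got <- pf_series(a, cfg)
    want <- oracle_pf_table(a, cfg)
    expect_equal(got$time, want$time)
    expect_equal(got$pf_ratio, want$pf)
    expect_equal(got$peep_at_time, want$peep)
  }
})

test_that("BI windows truncate at negatives and merge overlaps", {
  # positive at 72 h, no negatives -> [48 h, 96 h]
  w1 <- build_bi_windows(evidence_timeline(bi_positive_times = h(72)), cfg)
  expect_equal(w1$lo, h(48)); expect_equal(w1$hi, h(96))
  expect_false(w1$lo_open); expect_false(w1$hi_open)
  # negative at 80 h -> [48 h, 80 h)
  w2 <- build_bi_windows(evidence_timeline(h(72), h(80)), cfg)
  expect_equal(w2$hi, h(80)); expect_true(w2$hi_open)
  expect_true(in_bi_window(h(79), w2))
  expect_false(in_bi_window(h(80), w2))     # half-open at the negative
  expect_true(in_bi_window(h(48), w2))      # closed at the base endpoint
  # no positives -> empty set
  expect_equal(nrow(build_bi_windows(evidence_timeline(), cfg)), 0)
  # overlapping positives merge into one interval
  w3 <- build_bi_windows(evidence_timeline(c(h(72), h(84))), cfg)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$lo, w3$hi), c(h(48), h(108)))
})

test_that("window membership matches the 1-minute-grid oracle", {
  set.seed(13)
  for (i in 1:30) {
    pos <- sort(sample(seq(h(24), d(8), by = 30), sample(1:4, 1)))
    neg <- sort(sample(seq(0, d(9), by = 30), sample(0:4, 1)))
    delta <- sample(c(h(4), h(12), d(1), d(2)), 1)
    tl <- evidence_timeline(pos, neg)
    c2 <- berlin_config(delta_bi = delta)
    win <- build_bi_windows(tl, c2)
    grid <- seq(0, d(10), by = 60)
    expect_equal(in_bi_window(grid, win),
                 oracle_bi_valid_grid(grid, pos, neg, delta),
                 info = paste("case", i))
  }
})

test_that("qualifying events require both low P/F and adequate PEEP", {
  pf <- data.frame(time = c(1, 2, 3), pao2 = c(60, 95, 40),
                   fio2 = c(0.4, 0.21, 0.4),
                   pf_ratio = c(150, 95 / 0.21, 100),
                   peep_at_time = c(8, 8, 4))
  q <- qualifying_pf_events(pf, cfg)
  expect_equal(q$time, 1)                   # 452 > 300 dropped; PEEP 4 dropped
  pf$peep_at_time[3] <- NA
  expect_equal(nrow(qualifying_pf_events(pf, cfg)), 1)
})

test_that("candidate onset is the earliest qualifying time inside a window", {
  win <- build_bi_windows(evidence_timeline(h(72)), cfg)
  q <- data.frame(time = c(h(50), h(90)), pf_ratio = 150, peep_at_time = 8)
  expect_equal(candidate_onset(q, win), h(50))
  q2 <- data.frame(time = h(40), pf_ratio = 150, peep_at_time = 8)
  expect_true(is.na(candidate_onset(q2, win)))
  expect_true(is.na(candidate_onset(q, win[0, ])))
})

test_that("acuteness fails on early tracheostomy or a late onset", {
  trach5 <- mk_admission(procedures = data.frame(time = d(5),
                                                 kind = "tracheostomy"))
  expect_false(check_acuteness(trach5, d(6), cfg)$passed)
  late <- mk_admission(observations = obs_df(list(d(1), "peep", 8),
                                             list(d(1), "fio2", 0.4),
                                             list(d(1), "pao2", 60)))
  expect_false(check_acuteness(late, d(9), cfg)$passed)    # 8 d > 7 d horizon
  ok <- mk_admission(observations = obs_df(list(d(1), "peep", 8)),
                     procedures = data.frame(time = d(10),
                                             kind = "tracheostomy"))
  expect_true(check_acuteness(ok, d(3), cfg)$passed)
})

test_that("HF/FO origin check applies the attribution formula verbatim", {
  # evidence at day 2, onset day 3: 3 >= 2 - 5 -> HF/FO origin
  expect_false(check_hffo_origin(d(3), evidence_timeline(hffo_times = d(2)),
                                 cfg)$passed)
  # no HF/FO evidence -> pass
  expect_true(check_hffo_origin(d(3), evidence_timeline(), cfg)$passed)
  # evidence at day 10, onset day 3: 3 >= 10 - 5 is false -> pass
  expect_true(check_hffo_origin(d(3), evidence_timeline(hffo_times = d(10)),
                                cfg)$passed)
  # evidence *after* onset within the window still blocks (formula as stated)
  expect_false(check_hffo_origin(d(3), evidence_timeline(hffo_times = d(6)),
                                 cfg)$passed)
})

test_that("ventilation rule enforces 48 h with a terminal exception", {
  vent30 <- function(dispo, discharge) {
    mk_admission(vent = data.frame(intubation = h(10), extubation = h(40)),
                 disposition = dispo, discharge = discharge)
  }
  expect_false(check_ventilation_rule(vent30("home", d(10)), cfg)$passed)
  expect_true(check_ventilation_rule(vent30("expired", h(50)), cfg)$passed)
  expect_true(check_ventilation_rule(
    mk_admission(vent = data.frame(intubation = h(10),
                                   extubation = h(60))), cfg)$passed)
  # hospice discharge 40 h after intubation -> intubation branch applies
  expect_true(check_ventilation_rule(vent30("hospice", h(50)), cfg)$passed)
  # open episode runs to discharge
  open_ep <- mk_admission(vent = data.frame(intubation = h(10),
                                            extubation = NA_real_),
                          discharge = h(70))
  expect_true(check_ventilation_rule(open_ep, cfg)$passed)
})

test_that("severity derives from the minimum qualifying P/F near onset", {
  q <- function(times, pfs) data.frame(time = times, pf_ratio = pfs,
                                       peep_at_time = 8)
  expect_equal(assign_severity(q(h(50), 150), h(50), cfg), "moderate")
  expect_equal(assign_severity(q(h(50), 90), h(50), cfg), "severe")
  # a lower P/F outside the +/-24 h scan window is ignored
  expect_equal(assign_severity(q(c(h(50), h(80)), c(250, 180)), h(50), cfg),
               "mild")
})

test_that("detect_ards assembles the full verdict with a complete trace", {
  a <- mk_classic_admission()
  v <- detect_ards(a, evidence = classic_evidence())
  expect_true(v$ards)
  expect_equal(v$onset_time, h(50))
  expect_equal(v$severity, "moderate")
  expect_true(all(c("ventilation", "bilateral_infiltrates", "hypoxemia",
                    "acuteness", "hffo_origin", "severity") %in%
                    names(v$criteria_trace)))
  expect_true(all(vapply(v$criteria_trace, function(tr)
    nzchar(tr$detail), logical(1))))
  # HF/FO evidence at day 2 flips the verdict
  v2 <- detect_ards(a, evidence = classic_evidence(with_hffo = TRUE))
  expect_false(v2$ards)
  expect_equal(v2$failed_reason, "HF/FO origin")
  # no evidence at all -> no BI evidence
  v3 <- detect_ards(a, evidence = classic_evidence()[0, ])
  expect_false(v3$ards)
  expect_equal(v3$failed_reason, "no BI evidence")
  # neither models nor evidence is an error
  expect_error(detect_ards(a), "evidence")
})

test_that("verdict flag equals the conjunction of the component checks", {
  co <- generate_cohort(generator_config(n = 120, seed = 17))
  for (i in seq_along(co$admissions)) {
    a <- co$admissions[[i]]
    v <- detect_ards(a, evidence = co$evidence)
    tl <- evidence_timeline(
      bi_positive_times = co$evidence$time[
        co$evidence$admission_id == a$admission_id &
          co$evidence$kind == "bi_pos"],
      bi_negative_times = co$evidence$time[
        co$evidence$admission_id == a$admission_id &
          co$evidence$kind == "bi_neg"],
      hffo_times = co$evidence$time[
        co$evidence$admission_id == a$admission_id &
          co$evidence$kind == "hffo"])
    q <- qualifying_pf_events(pf_series(a, cfg), cfg)
    t0 <- candidate_onset(q, build_bi_windows(tl, cfg))
    conj <- check_ventilation_rule(a, cfg)$passed &&
      length(tl$bi_positive_times) > 0 && !is.na(t0) &&
      check_acuteness(a, t0, cfg)$passed &&
      check_hffo_origin(t0, tl, cfg)$passed
    expect_equal(v$ards, conj, info = a$admission_id)
  }
})

test_that("enlarging the BI window never flips positives negative (no negatives present)", {
  co <- generate_cohort(generator_config(
    n = 60, seed = 23,
    scenario_mix = c(classic_ards = 0.6, no_hypoxemia = 0.2,
                     hffo_confounded = 0.2)))
  keep <- co$labels$scenario != "rapid_resolution"
  deltas <- c(h(4), h(12), d(1), d(2), d(5))
  prev <- rep(FALSE, sum(keep))
  for (dl in deltas) {
    c2 <- berlin_config(delta_bi = dl)
    flags <- vapply(co$admissions[keep], function(a)
      detect_ards(a, evidence = co$evidence, config = c2)$ards, logical(1))
    expect_true(all(flags >= prev),
                info = sprintf("delta_bi %.0f min", dl))
    prev <- flags
  }
})
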