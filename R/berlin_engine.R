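#' @title Berlin-criteria decision engine
#' @name berlin_engine
#' @description
#' Temporal logic that turns one admission's structured observations,
#' ventilation episodes, procedures and note-level evidence into an ARDS
#' verdict with onset time, severity and a per-criterion trace. The four
#' Berlin criteria are evaluated conjunctively: (1) acute onset, proxied by
#' the absence of an early tracheostomy and by an onset horizon after the
#' first PEEP >= 5 record; (2) qualifying hypoxemia, PaO2/FiO2 <= 300 mmHg
#' while PEEP >= 5 cmH2O; (3) bilateral infiltrates on chest imaging, valid
#' within a window around each positive radiograph that shrinks at
#' intervening negative radiographs; (4) respiratory failure not primarily
#' attributable to heart failure / fluid overload.
NULL

#' Tunable thresholds and windows of the ARDS decision logic
#'
#' All durations are minutes. The defaults are the tuned operating point:
#' a 1-day validity window around bilateral-infiltrate (BI) evidence and a
#' 5-day window around heart-failure/fluid-overload (HF/FO) evidence, PEEP
#' threshold 5 cmH2O, P/F threshold 300 mmHg, a 7-day onset horizon after
#' the first PEEP >= 5 record, a 7-day early-tracheostomy window, and a
#' 48-hour minimum ventilation requirement with a 48-hour terminal-care
#' exception.
#'
#' @param delta_bi BI validity half-window (minutes; default 1 day).
#' @param delta_hffo HF/FO attribution window (minutes; default 5 days).
#' @param peep_min Minimum PEEP (cmH2O) for a qualifying measurement.
#' @param pf_max Maximum P/F ratio (mmHg) for a qualifying measurement.
#' @param onset_horizon Maximum delay of onset after the first PEEP >=
#'   `peep_min` record (minutes; default 7 days).
#' @param trach_window Tracheostomy-after-admission window that violates
#'   acuteness (minutes; default 7 days).
#' @param min_vent_hours Minimum total mechanical-ventilation duration
#'   (hours).
#' @param terminal_window_hours Exception window: death/hospice discharge
#'   within this many hours of an intubation or extubation waives the
#'   minimum-ventilation requirement.
#' @param fio2_pairing_lookback How far back (minutes) an FiO2 record may be
#'   to pair with a PaO2 measurement.
#' @param peep_staleness_limit Maximum age (minutes) of the
#'   last-observation-carried-forward PEEP at a PaO2 time.
#' @param severity_cutoffs Increasing P/F cutoffs `c(severe, moderate, mild)`
#'   in mmHg; the top value must equal `pf_max`.
#' @param severity_scan_window Half-width (minutes) of the window around
#'   onset scanned for the minimum qualifying P/F.
#' @param disabled_checks Character subset of
#'   `c("vent", "trach", "horizon", "hffo")`; used by ablation analyses.
#' @return Object of class `berlin_config`.
#' @export
berlin_config <- function(delta_bi = 1440,
                          delta_hffo = 5 * 1440,
                          peep_min = 5,
                          pf_max = 300,
                          onset_horizon = 7 * 1440,
                          trach_window = 7 * 1440,
                          min_vent_hours = 48,
                          terminal_window_hours = 48,
                          fio2_pairing_lookback = 240,
                          peep_staleness_limit = 480,
                          severity_cutoffs = c(severe = 100, moderate = 200,
                                               mild = 300),
                          severity_scan_window = 1440,
                          disabled_checks = character(0)) {
  durations <- c(delta_bi, delta_hffo, onset_horizon, trach_window,
                 fio2_pairing_lookback, peep_staleness_limit,
                 severity_scan_window)
  if (any(durations <= 0)) stop("all durations must be positive", call. = FALSE)
  if (length(severity_cutoffs) != 3L || any(diff(severity_cutoffs) <= 0)) {
    stop("severity_cutoffs must be three strictly increasing values",
         call. = FALSE)
  }
  if (abs(severity_cutoffs[[3]] - pf_max) > 1e-9) {
    stop("severity_cutoffs must be topped by pf_max", call. = FALSE)
  }
  bad <- setdiff(disabled_checks, c("vent", "trach", "horizon", "hffo"))
  if (length(bad) > 0L) stop("unknown check(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  structure(list(delta_bi = delta_bi, delta_hffo = delta_hffo,
                 peep_min = peep_min, pf_max = pf_max,
                 onset_horizon = onset_horizon, trach_window = trach_window,
                 min_vent_hours = min_vent_hours,
                 terminal_window_hours = terminal_window_hours,
                 fio2_pairing_lookback = fio2_pairing_lookback,
                 peep_staleness_limit = peep_staleness_limit,
                 severity_cutoffs = severity_cutoffs,
                 severity_scan_window = severity_scan_window,
                 disabled_checks = disabled_checks),
            class = "berlin_config")
}

#' Timestamped note-level evidence for one admission
#'
#' @param bi_positive_times Times (minutes since admission) of chest
#'   radiographs with bilateral-infiltrate evidence.
#' @param bi_negative_times Times of radiographs without such evidence.
#' @param hffo_times Times of any note (radiograph or echocardiogram) with
#'   heart-failure/fluid-overload evidence; the earliest is the HF/FO
#'   reference time.
#' @param note_ids Optional list with character vectors `bi_pos`, `bi_neg`,
#'   `hffo` tracing each entry to a note.
#' @return Object of class `evidence_timeline`.
#' @export
evidence_timeline <- function(bi_positive_times = numeric(0),
                              bi_negative_times = numeric(0),
                              hffo_times = numeric(0),
                              note_ids = NULL) {
  ord_p <- order(bi_positive_times)
  ord_n <- order(bi_negative_times)
  ord_h <- order(hffo_times)
  if (is.null(note_ids)) {
    note_ids <- list(bi_pos = paste0("bi_pos_", seq_along(bi_positive_times)),
                     bi_neg = paste0("bi_neg_", seq_along(bi_negative_times)),
                     hffo = paste0("hffo_", seq_along(hffo_times)))
  }
  structure(list(bi_positive_times = as.numeric(bi_positive_times)[ord_p],
                 bi_negative_times = as.numeric(bi_negative_times)[ord_n],
                 hffo_times = as.numeric(hffo_times)[ord_h],
                 note_ids = list(bi_pos = note_ids$bi_pos[ord_p],
                                 bi_neg = note_ids$bi_neg[ord_n],
                                 hffo = note_ids$hffo[ord_h])),
            class = "evidence_timeline")
}

#' Pair PaO2 with FiO2 and PEEP into P/F measurements
#'
#' One measurement per PaO2 record that has an FiO2 at-or-before it within
#' `config$fio2_pairing_lookback` minutes (the most recent such FiO2 is
#' used). PEEP is carried forward from the last record at-or-before the PaO2
#' time, but only within `config$peep_staleness_limit`; otherwise it is
#' absent (`NA`). PaO2 records without a pairable FiO2 are skipped and
#' counted in the `n_unpaired` attribute.
#'
#' @param admission An `admission_record` with normalized observations.
#' @param config A [berlin_config()].
#' @return Data frame with `time`, `pao2`, `fio2`, `pf_ratio`,
#'   `peep_at_time`.
#' @export
pf_series <- function(admission, config = berlin_config()) {
  pao2 <- obs_series(admission, "pao2")
  fio2 <- obs_series(admission, "fio2")
  peep <- obs_series(admission, "peep")
  if (nrow(pao2) == 0L) {
    out <- data.frame(time = numeric(), pao2 = numeric(), fio2 = numeric(),
                      pf_ratio = numeric(), peep_at_time = numeric())
    attr(out, "n_unpaired") <- 0L
    return(out)
  }
  fi_idx <- findInterval(pao2$time, fio2$time)     # last fio2 at-or-before
  fi_time <- ifelse(fi_idx >= 1L, fio2$time[pmax(fi_idx, 1L)], -Inf)
  fi_val <- ifelse(fi_idx >= 1L, fio2$value[pmax(fi_idx, 1L)], NA_real_)
  paired <- fi_idx >= 1L & (pao2$time - fi_time) <= config$fio2_pairing_lookback
  pe_idx <- findInterval(pao2$time, peep$time)
  pe_time <- ifelse(pe_idx >= 1L, peep$time[pmax(pe_idx, 1L)], -Inf)
  pe_val <- ifelse(pe_idx >= 1L & (pao2$time - pe_time) <= config$peep_staleness_limit,
                   peep$value[pmax(pe_idx, 1L)], NA_real_)
  out <- data.frame(time = pao2$time[paired],
                    pao2 = pao2$value[paired],
                    fio2 = fi_val[paired],
                    pf_ratio = pao2$value[paired] / fi_val[paired],
                    peep_at_time = pe_val[paired])
  attr(out, "n_unpaired") <- sum(!paired)
  out
}

#' Build bilateral-infiltrate validity windows
#'
#' Each positive radiograph at time `T` contributes a base interval
#' `[T - delta_bi, T + delta_bi]`. The interval is truncated by the nearest
#' negative radiograph on each side (the window is half-open at a truncating
#' endpoint, so the negative's own time is excluded), and overlapping
#' intervals are merged.
#'
#' @param timeline An [evidence_timeline()].
#' @param config A [berlin_config()].
#' @return Data frame of disjoint intervals with columns `lo`, `hi`,
#'   `lo_open`, `hi_open`.
#' @export
build_bi_windows <- function(timeline, config = berlin_config()) {
  pos <- timeline$bi_positive_times
  neg <- timeline$bi_negative_times
  empty <- data.frame(lo = numeric(), hi = numeric(),
                      lo_open = logical(), hi_open = logical())
  if (length(pos) == 0L) return(empty)
  win <- do.call(rbind, lapply(pos, function(tb) {
    lo <- tb - config$delta_bi; lo_open <- FALSE
    hi <- tb + config$delta_bi; hi_open <- FALSE
    below <- neg[neg < tb]
    if (length(below) > 0L && max(below) > lo) {
      lo <- max(below); lo_open <- TRUE
    }
    above <- neg[neg > tb]
    if (length(above) > 0L && min(above) < hi) {
      hi <- min(above); hi_open <- TRUE
    }
    data.frame(lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
  }))
  # drop intervals emptied by truncation
  keep <- win$lo < win$hi | (win$lo == win$hi & !win$lo_open & !win$hi_open)
  win <- win[keep, , drop = FALSE]
  if (nrow(win) <= 1L) { rownames(win) <- NULL; return(win) }
  win <- win[order(win$lo, win$lo_open), , drop = FALSE]
  merged <- win[1, , drop = FALSE]
  for (i in 2:nrow(win)) {
    cur <- merged[nrow(merged), ]
    nxt <- win[i, ]
    touches <- nxt$lo < cur$hi ||
      (nxt$lo == cur$hi && !(cur$hi_open && nxt$lo_open))
    if (touches) {
      if (nxt$hi > cur$hi || (nxt$hi == cur$hi && !nxt$hi_open)) {
        merged$hi[nrow(merged)] <- nxt$hi
        merged$hi_open[nrow(merged)] <- nxt$hi_open
      }
    } else {
      merged <- rbind(merged, nxt)
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Test membership of times in a window set
#'
#' @param t Numeric vector of times (minutes since admission).
#' @param windows Window table from [build_bi_windows()].
#' @return Logical vector.
#' @export
in_bi_window <- function(t, windows) {
  if (nrow(windows) == 0L) return(rep(FALSE, length(t)))
  vapply(t, function(x) {
    any(ifelse(windows$lo_open, x > windows$lo, x >= windows$lo) &
        ifelse(windows$hi_open, x < windows$hi, x <= windows$hi))
  }, logical(1))
}

#' Keep measurements meeting the hypoxemia criterion
#'
#' Filters to measurements with P/F ratio <= `pf_max` and a present PEEP
#' >= `peep_min`.
#'
#' @param pf P/F measurement table from [pf_series()].
#' @param config A [berlin_config()].
#' @return Subset of `pf`.
#' @export
qualifying_pf_events <- function(pf, config = berlin_config()) {
  keep <- pf$pf_ratio <= config$pf_max &
    !is.na(pf$peep_at_time) & pf$peep_at_time >= config$peep_min
  out <- pf[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Earliest qualifying hypoxemia inside a BI window
#'
#' @param qualifying Qualifying measurements from [qualifying_pf_events()].
#' @param bi_windows Window table from [build_bi_windows()].
#' @return The candidate onset time in minutes, or `NA_real_` when no
#'   qualifying measurement falls inside any window.
#' @export
candidate_onset <- function(qualifying, bi_windows) {
  if (nrow(qualifying) == 0L || nrow(bi_windows) == 0L) return(NA_real_)
  inside <- in_bi_window(qualifying$time, bi_windows)
  if (!any(inside)) return(NA_real_)
  min(qualifying$time[inside])
}

#' Acute-onset check
#'
#' Fails when a tracheostomy occurs within `trach_window` of admission, or
#' when the candidate onset is more than `onset_horizon` after the first
#' PEEP >= `peep_min` record. The two sub-checks can be disabled
#' independently through `config$disabled_checks` (`"trach"`, `"horizon"`).
#'
#' @param admission An `admission_record`.
#' @param t0 Candidate onset (minutes since admission).
#' @param config A [berlin_config()].
#' @return List with `passed` and `detail`.
#' @export
check_acuteness <- function(admission, t0, config = berlin_config()) {
  pr <- admission$procedures
  trach <- pr$time[pr$kind == "tracheostomy"]
  if (!"trach" %in% config$disabled_checks &&
      length(trach) > 0L && any(trach <= config$trach_window)) {
    return(list(passed = FALSE,
                detail = sprintf("tracheostomy at %.0f min, within %.0f min of admission",
                                 min(trach[trach <= config$trach_window]),
                                 config$trach_window)))
  }
  peep <- obs_series(admission, "peep")
  first_peep <- suppressWarnings(min(peep$time[peep$value >= config$peep_min]))
  if (!"horizon" %in% config$disabled_checks) {
    if (!is.finite(first_peep)) {
      return(list(passed = FALSE, detail = "no PEEP >= threshold record"))
    }
    if (t0 - first_peep > config$onset_horizon) {
      return(list(passed = FALSE,
                  detail = sprintf("onset %.0f min after first PEEP >= %g (limit %.0f)",
                                   t0 - first_peep, config$peep_min,
                                   config$onset_horizon)))
    }
  }
  list(passed = TRUE,
       detail = sprintf("no early tracheostomy; onset %.0f min after first PEEP >= %g",
                        if (is.finite(first_peep)) t0 - first_peep else NA_real_,
                        config$peep_min))
}

#' Heart-failure/fluid-overload origin check
#'
#' With `T0_hffo` the earliest HF/FO evidence time, the check fails iff
#' `t0 >= T0_hffo - delta_hffo` — HF/FO is then identified as the origin of
#' respiratory failure. Applied exactly as stated, this also blocks ARDS
#' when HF/FO evidence postdates the onset by up to `delta_hffo`. No HF/FO
#' evidence passes trivially.
#'
#' @param t0 Candidate onset (minutes).
#' @param timeline An [evidence_timeline()].
#' @param config A [berlin_config()].
#' @return List with `passed` and `detail`.
#' @export
check_hffo_origin <- function(t0, timeline, config = berlin_config()) {
  if ("hffo" %in% config$disabled_checks) {
    return(list(passed = TRUE, detail = "HF/FO check disabled"))
  }
  if (length(timeline$hffo_times) == 0L) {
    return(list(passed = TRUE, detail = "no HF/FO evidence"))
  }
  t_hffo <- min(timeline$hffo_times)
  if (t0 >= t_hffo - config$delta_hffo) {
    list(passed = FALSE,
         detail = sprintf("HF/FO origin: onset %.0f >= %.0f - %.0f",
                          t0, t_hffo, config$delta_hffo))
  } else {
    list(passed = TRUE,
         detail = sprintf("earliest HF/FO evidence at %.0f min is beyond the %.0f-min window",
                          t_hffo, config$delta_hffo))
  }
}

#' Minimum-ventilation check
#'
#' Total ventilated time (open episodes run to discharge) must reach
#' `min_vent_hours`. Shorter ventilation is allowed only for admissions that
#' expired or were discharged to hospice within `terminal_window_hours` of
#' any intubation or extubation time.
#'
#' @param admission An `admission_record`.
#' @param config A [berlin_config()].
#' @return List with `passed` and `detail`.
#' @export
check_ventilation_rule <- function(admission, config = berlin_config()) {
  if ("vent" %in% config$disabled_checks) {
    return(list(passed = TRUE, detail = "ventilation check disabled"))
  }
  ve <- admission$vent_episodes
  ends <- ifelse(is.na(ve$extubation), admission$discharge_time, ve$extubation)
  total_min <- sum(pmax(ends - ve$intubation, 0))
  if (total_min >= config$min_vent_hours * 60) {
    return(list(passed = TRUE,
                detail = sprintf("ventilated %.1f h", total_min / 60)))
  }
  event_times <- c(ve$intubation, ends)
  terminal <- admission$disposition %in% c("expired", "hospice") &&
    length(event_times) > 0L &&
    any(admission$discharge_time <= event_times + config$terminal_window_hours * 60)
  if (terminal) {
    list(passed = TRUE,
         detail = sprintf("ventilated %.1f h; terminal exception (%s within %g h of intubation/extubation)",
                          total_min / 60, admission$disposition,
                          config$terminal_window_hours))
  } else {
    list(passed = FALSE,
         detail = sprintf("ventilated %.1f h < %g h, no terminal exception",
                          total_min / 60, config$min_vent_hours))
  }
}

#' Berlin severity stratum at onset
#'
#' Severity is read from the minimum qualifying P/F ratio within
#' `severity_scan_window` of the onset: `<= severe cutoff` severe,
#' `(severe, moderate]` moderate, `(moderate, mild]` mild.
#'
#' @param qualifying Qualifying measurements.
#' @param t0 Onset time (minutes).
#' @param config A [berlin_config()].
#' @return `"mild"`, `"moderate"` or `"severe"` (or `NA_character_` when no
#'   qualifying measurement lies in the scan window).
#' @export
assign_severity <- function(qualifying, t0, config = berlin_config()) {
  near <- abs(qualifying$time - t0) <= config$severity_scan_window
  if (!any(near)) return(NA_character_)
  min_pf <- min(qualifying$pf_ratio[near])
  cuts <- config$severity_cutoffs
  if (min_pf <= cuts[[1]]) "severe"
  else if (min_pf <= cuts[[2]]) "moderate"
  else "mild"
}

# Build the evidence timeline, either from an injected evidence table
# (columns time, kind in {bi_pos, bi_neg, hffo}, optional note_id) or by
# running the text classifiers over the admission's notes.
build_evidence <- function(admission, models = NULL, evidence = NULL) {
  if (!is.null(evidence)) {
    if ("admission_id" %in% names(evidence)) {
      evidence <- evidence[evidence$admission_id == admission$admission_id, ,
                           drop = FALSE]
    }
    if (!"note_id" %in% names(evidence)) {
      evidence[["note_id"]] <- if (nrow(evidence) > 0)
        paste0("ev", seq_len(nrow(evidence))) else character(0)
    }
    return(evidence_timeline(
      bi_positive_times = evidence$time[evidence$kind == "bi_pos"],
      bi_negative_times = evidence$time[evidence$kind == "bi_neg"],
      hffo_times = evidence$time[evidence$kind == "hffo"],
      note_ids = list(bi_pos = evidence$note_id[evidence$kind == "bi_pos"],
                      bi_neg = evidence$note_id[evidence$kind == "bi_neg"],
                      hffo = evidence$note_id[evidence$kind == "hffo"])))
  }
  if (is.null(models) || is.null(models$BI)) {
    stop("detect_ards needs either trained models (at least BI) or an injected evidence table",
         call. = FALSE)
  }
  notes <- admission$notes
  bi_pos <- numeric(0); bi_neg <- numeric(0); hffo <- numeric(0)
  ids_pos <- character(0); ids_neg <- character(0); ids_h <- character(0)
  for (i in seq_len(nrow(notes))) {
    note <- notes[i, ]
    if (note$category == "chest_radiograph") {
      lab <- classify_report(note, models$BI)$label
      if (lab == "positive") {
        bi_pos <- c(bi_pos, note$time); ids_pos <- c(ids_pos, note$note_id)
      } else {
        bi_neg <- c(bi_neg, note$time); ids_neg <- c(ids_neg, note$note_id)
      }
      if (!is.null(models$HFFO_radiology) &&
          classify_report(note, models$HFFO_radiology)$label == "positive") {
        hffo <- c(hffo, note$time); ids_h <- c(ids_h, note$note_id)
      }
    } else if (note$category == "echo" && !is.null(models$HFFO_echo)) {
      if (classify_report(note, models$HFFO_echo)$label == "positive") {
        hffo <- c(hffo, note$time); ids_h <- c(ids_h, note$note_id)
      }
    }
  }
  evidence_timeline(bi_pos, bi_neg, hffo,
                    note_ids = list(bi_pos = ids_pos, bi_neg = ids_neg,
                                    hffo = ids_h))
}

make_verdict <- function(admission_id, ards, onset = NA_real_,
                         severity = NA_character_, trace = list(),
                         failed_reason = NA_character_) {
  structure(list(admission_id = admission_id, ards = ards,
                 onset_time = onset, severity = severity,
                 criteria_trace = trace, failed_reason = failed_reason),
            class = "ards_verdict")
}

#' Detect ARDS for one admission
#'
#' Evaluates the Berlin criteria in the order: minimum-ventilation rule,
#' bilateral-infiltrate evidence and windows, qualifying hypoxemia and
#' candidate onset, acuteness (tracheostomy proxy and onset horizon), and
#' heart-failure/fluid-overload origin. The criteria are conjunctive, so the
#' order does not affect the verdict, only which failure is reported first.
#'
#' @param admission An `admission_record`.
#' @param models Optional named list of trained classifiers (`BI`,
#'   `HFFO_radiology`, `HFFO_echo`) applied to the admission's notes.
#' @param evidence Optional injected evidence table (columns `time`, `kind`
#'   in `bi_pos`/`bi_neg`/`hffo`, optional `admission_id`, `note_id`); when
#'   given, the classifiers are bypassed.
#' @param config A [berlin_config()].
#' @return An `ards_verdict`: `ards` flag, `onset_time` (minutes since
#'   admission), `severity`, `criteria_trace`, `failed_reason`.
#' @export
detect_ards <- function(admission, models = NULL, evidence = NULL,
                        config = berlin_config()) {
  trace <- list()

  vent <- check_ventilation_rule(admission, config)
  trace$ventilation <- vent
  if (!vent$passed) {
    return(make_verdict(admission$admission_id, FALSE, trace = trace,
                        failed_reason = "ventilation"))
  }

  timeline <- build_evidence(admission, models, evidence)
  trace$bilateral_infiltrates <- list(
    passed = length(timeline$bi_positive_times) > 0L,
    detail = sprintf("%d positive, %d negative chest radiograph(s)",
                     length(timeline$bi_positive_times),
                     length(timeline$bi_negative_times)))
  if (length(timeline$bi_positive_times) == 0L) {
    return(make_verdict(admission$admission_id, FALSE, trace = trace,
                        failed_reason = "no BI evidence"))
  }

  pf <- pf_series(admission, config)
  qualifying <- qualifying_pf_events(pf, config)
  windows <- build_bi_windows(timeline, config)
  t0 <- candidate_onset(qualifying, windows)
  trace$hypoxemia <- list(
    passed = !is.na(t0),
    detail = sprintf("%d P/F measurement(s) (%d unpairable PaO2), %d qualifying, %d BI window(s)%s",
                     nrow(pf), attr(pf, "n_unpaired"), nrow(qualifying),
                     nrow(windows),
                     if (is.na(t0)) "" else sprintf(", onset %.0f min", t0)))
  if (is.na(t0)) {
    return(make_verdict(admission$admission_id, FALSE, trace = trace,
                        failed_reason = "no qualifying hypoxemia within a BI window"))
  }

  acute <- check_acuteness(admission, t0, config)
  trace$acuteness <- acute
  if (!acute$passed) {
    return(make_verdict(admission$admission_id, FALSE, trace = trace,
                        failed_reason = "acuteness"))
  }

  hffo <- check_hffo_origin(t0, timeline, config)
  trace$hffo_origin <- hffo
  if (!hffo$passed) {
    return(make_verdict(admission$admission_id, FALSE, trace = trace,
                        failed_reason = "HF/FO origin"))
  }

  severity <- assign_severity(qualifying, t0, config)
  trace$severity <- list(passed = TRUE,
                         detail = sprintf("minimum qualifying P/F within +/-%.0f min of onset -> %s",
                                          config$severity_scan_window, severity))
  make_verdict(admission$admission_id, TRUE, onset = t0, severity = severity,
               trace = trace)
}

#' @export
print.ards_verdict <- function(x, ...) {
  if (x$ards) {
    cat(sprintf("<ards_verdict %s: ARDS, onset %.0f min (day %.1f), %s>\n",
                x$admission_id, x$onset_time, x$onset_time / 1440, x$severity))
  } else {
    cat(sprintf("<ards_verdict %s: not ARDS (%s)>\n", x$admission_id,
                x$failed_reason))
  }
  invisible(x)
}

#' Detect ARDS across a cohort
#'
#' @param admissions List of `admission_record` objects.
#' @param models,evidence,config Passed to [detect_ards()]; `evidence` may
#'   hold all admissions (filtered by `admission_id`).
#' @return List of `ards_verdict` objects, one per admission.
#' @export
detect_cohort <- function(admissions, models = NULL, evidence = NULL,
                          config = berlin_config()) {
  lapply(admissions, detect_ards, models = models, evidence = evidence,
         config = config)
}

#' Flatten verdicts to a data frame
#'
#' @param verdicts List of `ards_verdict` objects.
#' @return Data frame with `admission_id`, `ards`, `onset_time`, `severity`,
#'   `failed_reason`.
#' @export
verdicts_to_df <- function(verdicts) {
  do.call(rbind, lapply(verdicts, function(v) data.frame(
    admission_id = v$admission_id, ards = v$ards,
    onset_time = v$onset_time, severity = v$severity,
    failed_reason = v$failed_reason, stringsAsFactors = FALSE)))
}
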