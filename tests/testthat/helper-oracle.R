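# Brute-force reference implementation of the decision logic, written
# independently of the engine: bilateral-infiltrate validity is evaluated
# pointwise on a 1-minute grid, P/F pairing by exhaustive scan over all
# (PaO2, FiO2) candidate pairs, and every rule is re-derived from first
# principles. Used to verify detect_ards on synthetic admissions.

oracle_pf_table <- function(adm, cfg) {
  obs <- adm$observations
  pao2 <- obs[obs$variable == "pao2", ]
  fio2 <- obs[obs$variable == "fio2", ]
  peep <- obs[obs$variable == "peep", ]
  rows <- lapply(seq_len(nrow(pao2)), function(i) {
    t <- pao2$time[i]
    cand <- which(fio2$time <= t & t - fio2$time <= cfg$fio2_pairing_lookback)
    if (length(cand) == 0L) return(NULL)
    pick <- cand[which.max(fio2$time[cand])]
    pcand <- which(peep$time <= t & t - peep$time <= cfg$peep_staleness_limit)
    pv <- if (length(pcand) == 0L) NA_real_
          else peep$value[pcand[which.max(peep$time[pcand])]]
    data.frame(time = t, pf = pao2$value[i] / fio2$value[pick], peep = pv)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(time = numeric(), pf = numeric(),
                               peep = numeric()) else out
}

# validity of minute m: some positive radiograph at tb with |m - tb| <=
# delta and no negative radiograph strictly between tb and m (inclusive of
# m itself, exclusive of tb)
oracle_bi_valid_grid <- function(minutes, pos, neg, delta) {
  valid <- rep(FALSE, length(minutes))
  for (tb in pos) {
    ok <- abs(minutes - tb) <= delta
    up <- neg[neg > tb]
    if (length(up) > 0L) ok <- ok & minutes < min(up)
    lo <- neg[neg < tb]
    if (length(lo) > 0L) ok <- ok & minutes > max(lo)
    valid <- valid | ok
  }
  valid
}

oracle_detect <- function(adm, evidence, cfg = berlin_config()) {
  neg_out <- function(reason) list(ards = FALSE, onset = NA_real_,
                                   severity = NA_character_, reason = reason)
  ve <- adm$vent_episodes
  ends <- ifelse(is.na(ve$extubation), adm$discharge_time, ve$extubation)
  total <- sum(ends - ve$intubation)
  vent_ok <- total >= cfg$min_vent_hours * 60 ||
    (adm$disposition %in% c("expired", "hospice") &&
     length(ends) > 0L &&
     any(adm$discharge_time <= c(ve$intubation, ends) +
           cfg$terminal_window_hours * 60))
  if (!vent_ok) return(neg_out("ventilation"))

  ev <- evidence[evidence$admission_id == adm$admission_id, , drop = FALSE]
  pos <- ev$time[ev$kind == "bi_pos"]
  neg <- ev$time[ev$kind == "bi_neg"]
  hf <- ev$time[ev$kind == "hffo"]
  if (length(pos) == 0L) return(neg_out("no BI evidence"))

  pf <- oracle_pf_table(adm, cfg)
  qual <- pf[pf$pf <= cfg$pf_max & !is.na(pf$peep) & pf$peep >= cfg$peep_min, ,
             drop = FALSE]
  stopifnot(all(qual$time == round(qual$time)), all(qual$time >= 0))
  t_max <- ceiling(max(c(adm$discharge_time, pos, neg, qual$time, 0)) +
                   cfg$delta_bi)
  grid <- 0:t_max
  valid <- oracle_bi_valid_grid(grid, pos, neg, cfg$delta_bi)
  hit <- valid[qual$time + 1L]
  if (nrow(qual) == 0L || !any(hit)) {
    return(neg_out("no qualifying hypoxemia within a BI window"))
  }
  t0 <- min(qual$time[hit])

  trach <- adm$procedures$time[adm$procedures$kind == "tracheostomy"]
  if (length(trach) > 0L && any(trach <= cfg$trach_window)) {
    return(neg_out("acuteness"))
  }
  peep <- adm$observations[adm$observations$variable == "peep", ]
  first_peep <- min(peep$time[peep$value >= cfg$peep_min])
  if (t0 - first_peep > cfg$onset_horizon) return(neg_out("acuteness"))

  if (length(hf) > 0L && t0 >= min(hf) - cfg$delta_hffo) {
    return(neg_out("HF/FO origin"))
  }

  near <- abs(qual$time - t0) <= cfg$severity_scan_window
  mpf <- min(qual$pf[near])
  sev <- if (mpf <= cfg$severity_cutoffs[[1]]) "severe"
         else if (mpf <= cfg$severity_cutoffs[[2]]) "moderate"
         else "mild"
  list(ards = TRUE, onset = t0, severity = sev, reason = NA_character_)
}
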