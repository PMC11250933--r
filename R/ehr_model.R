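#' @title EHR admission data model
#' @name ehr_model
#' @description
#' Typed containers for one hospital admission: structured observations
#' (PaO2, FiO2, PEEP), ventilation episodes, procedures, ICD codes and
#' timestamped free-text notes. All event times are stored internally as
#' minutes since admission (numeric), which removes timezone/DST ambiguity;
#' the absolute admission timestamp is kept only for input/output.
NULL

.DISPOSITIONS <- c("expired", "hospice", "home", "facility")
.OBS_VARIABLES <- c("pao2", "fio2", "peep")
.NOTE_CATEGORIES <- c("chest_radiograph", "echo")

#' Construct an admission record
#'
#' @param admission_id Character scalar identifier.
#' @param age Age in years.
#' @param admit_time Absolute admission timestamp (`POSIXct`, UTC) used only
#'   for reading/writing; internal times are minutes since admission.
#' @param discharge_time Discharge time, minutes since admission.
#' @param disposition One of `"expired"`, `"hospice"`, `"home"`, `"facility"`.
#' @param icd_codes Data frame with columns `code` (dot-stripped ICD-9 string)
#'   and `is_primary` (logical).
#' @param observations Data frame with columns `time` (minutes), `variable`
#'   (one of `"pao2"`, `"fio2"`, `"peep"`) and `value`. FiO2 must already be a
#'   fraction in \[0.21, 1\]; see [normalize_fio2()].
#' @param vent_episodes Data frame with columns `intubation`, `extubation`
#'   (minutes; `NA` extubation means still ventilated at discharge).
#' @param procedures Data frame with columns `time` (minutes) and `kind`
#'   (`"tracheostomy"` or `"other"`).
#' @param notes Data frame with columns `note_id`, `time` (minutes),
#'   `category` (`"chest_radiograph"` or `"echo"`), `text`.
#' @return An object of class `admission_record`.
#' @export
admission_record <- function(admission_id, age, admit_time, discharge_time,
                             disposition,
                             icd_codes = empty_icd(),
                             observations = empty_observations(),
                             vent_episodes = empty_vent(),
                             procedures = empty_procedures(),
                             notes = empty_notes()) {
  stopifnot(is.character(admission_id), length(admission_id) == 1L,
            nzchar(admission_id))
  disposition <- match.arg(disposition, .DISPOSITIONS)
  if (!inherits(admit_time, "POSIXct")) {
    admit_time <- as.POSIXct(admit_time, tz = "UTC")
  }
  discharge_time <- as.numeric(discharge_time)
  if (!is.finite(discharge_time) || discharge_time < 0) {
    stop("discharge_time must be a non-negative duration in minutes ",
         "(admit_time <= discharge_time)", call. = FALSE)
  }
  observations <- validate_observations(observations)
  vent_episodes <- validate_vent(vent_episodes)
  procedures <- validate_procedures(procedures)
  notes <- validate_notes(notes)
  icd_codes <- validate_icd(icd_codes)

  rec <- structure(list(
    admission_id = admission_id,
    age = as.numeric(age),
    admit_time = admit_time,
    discharge_time = discharge_time,
    disposition = disposition,
    icd_codes = icd_codes,
    observations = observations,
    vent_episodes = vent_episodes,
    procedures = procedures,
    notes = notes
  ), class = "admission_record")
  flag_out_of_span_events(rec)
}

empty_icd <- function() data.frame(code = character(), is_primary = logical(),
                                   stringsAsFactors = FALSE)
empty_observations <- function() data.frame(time = numeric(),
                                            variable = character(),
                                            value = numeric(),
                                            stringsAsFactors = FALSE)
empty_vent <- function() data.frame(intubation = numeric(),
                                    extubation = numeric())
empty_procedures <- function() data.frame(time = numeric(), kind = character(),
                                          stringsAsFactors = FALSE)
empty_notes <- function() data.frame(note_id = character(), time = numeric(),
                                     category = character(), text = character(),
                                     stringsAsFactors = FALSE)

validate_observations <- function(obs) {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) return(empty_observations())
  stopifnot(all(c("time", "variable", "value") %in% names(obs)))
  bad <- !obs$variable %in% .OBS_VARIABLES
  if (any(bad)) stop("unknown observation variable: ",
                     paste(unique(obs$variable[bad]), collapse = ", "),
                     call. = FALSE)
  fio2 <- obs$variable == "fio2"
  if (any(fio2 & (obs$value < 0.21 - 1e-9 | obs$value > 1 + 1e-9))) {
    stop("FiO2 observations must be fractions in [0.21, 1]; ",
         "run normalize_fio2() first", call. = FALSE)
  }
  if (any(obs$value[obs$variable == "pao2"] <= 0)) {
    stop("PaO2 must be positive", call. = FALSE)
  }
  if (any(obs$value[obs$variable == "peep"] < 0)) {
    stop("PEEP must be non-negative", call. = FALSE)
  }
  obs <- obs[order(obs$time), c("time", "variable", "value")]
  rownames(obs) <- NULL
  obs
}

validate_vent <- function(vent) {
  vent <- as.data.frame(vent)
  if (nrow(vent) == 0L) return(empty_vent())
  stopifnot(all(c("intubation", "extubation") %in% names(vent)))
  closed <- !is.na(vent$extubation)
  if (any(closed & vent$extubation <= vent$intubation)) {
    stop("intubation_time must precede extubation_time", call. = FALSE)
  }
  vent <- vent[order(vent$intubation), c("intubation", "extubation")]
  if (nrow(vent) > 1L) {
    ends <- ifelse(is.na(vent$extubation), Inf, vent$extubation)
    if (any(vent$intubation[-1L] < ends[-nrow(vent)])) {
      stop("ventilation episodes must not overlap", call. = FALSE)
    }
  }
  rownames(vent) <- NULL
  vent
}

validate_procedures <- function(pr) {
  pr <- as.data.frame(pr, stringsAsFactors = FALSE)
  if (nrow(pr) == 0L) return(empty_procedures())
  stopifnot(all(c("time", "kind") %in% names(pr)))
  pr$kind <- ifelse(pr$kind == "tracheostomy", "tracheostomy", "other")
  pr <- pr[order(pr$time), c("time", "kind")]
  rownames(pr) <- NULL
  pr
}

validate_notes <- function(notes) {
  notes <- as.data.frame(notes, stringsAsFactors = FALSE)
  if (nrow(notes) == 0L) return(empty_notes())
  stopifnot(all(c("note_id", "time", "category", "text") %in% names(notes)))
  bad <- !notes$category %in% .NOTE_CATEGORIES
  if (any(bad)) stop("unknown note category: ",
                     paste(unique(notes$category[bad]), collapse = ", "),
                     call. = FALSE)
  notes$text[is.na(notes$text)] <- ""
  notes <- notes[order(notes$time), c("note_id", "time", "category", "text")]
  rownames(notes) <- NULL
  notes
}

validate_icd <- function(icd) {
  icd <- as.data.frame(icd, stringsAsFactors = FALSE)
  if (nrow(icd) == 0L) return(empty_icd())
  stopifnot(all(c("code", "is_primary") %in% names(icd)))
  icd$code <- gsub(".", "", as.character(icd$code), fixed = TRUE)
  icd$is_primary <- as.logical(icd$is_primary)
  icd[, c("code", "is_primary")]
}

# Events must fall within [admit - 24h, discharge + 24h]; out-of-span events
# are kept but flagged so downstream users can audit them.
flag_out_of_span_events <- function(rec) {
  lo <- -24 * 60
  hi <- rec$discharge_time + 24 * 60
  times <- c(rec$observations$time, rec$procedures$time, rec$notes$time,
             rec$vent_episodes$intubation,
             rec$vent_episodes$extubation[!is.na(rec$vent_episodes$extubation)])
  n_out <- sum(times < lo | times > hi)
  attr(rec, "n_out_of_span") <- n_out
  if (n_out > 0L) {
    warning(sprintf("admission %s: %d event(s) outside [admit-24h, discharge+24h]",
                    rec$admission_id, n_out), call. = FALSE)
  }
  rec
}

#' @export
print.admission_record <- function(x, ...) {
  cat(sprintf("<admission_record %s>\n", x$admission_id))
  cat(sprintf("  age %.0f, disposition %s, LOS %.1f d\n",
              x$age, x$disposition, x$discharge_time / 1440))
  tab <- table(factor(x$observations$variable, levels = .OBS_VARIABLES))
  cat(sprintf("  observations: pao2=%d fio2=%d peep=%d\n",
              tab[["pao2"]], tab[["fio2"]], tab[["peep"]]))
  cat(sprintf("  vent episodes: %d, procedures: %d, notes: %d, icd codes: %d\n",
              nrow(x$vent_episodes), nrow(x$procedures), nrow(x$notes),
              nrow(x$icd_codes)))
  invisible(x)
}

#' Extract one observation series from an admission
#'
#' @param admission An `admission_record`.
#' @param variable `"pao2"`, `"fio2"` or `"peep"`.
#' @return Data frame with `time` (minutes since admission) and `value`,
#'   time-ordered.
#' @export
obs_series <- function(admission, variable) {
  variable <- match.arg(variable, .OBS_VARIABLES)
  obs <- admission$observations
  out <- obs[obs$variable == variable, c("time", "value")]
  rownames(out) <- NULL
  out
}

#' Normalize FiO2 values to fractions
#'
#' EHR exports record inspired-oxygen fraction in two dialects: a fraction in
#' (0, 1\] or a percentage in \[21, 100\]. Values greater than 1 are
#' interpreted as percent and divided by 100; values at or below 1 pass
#' through (so `1.0` means 100% oxygen, not 1%). Values in the open interval
#' (1, 21) are physiologically meaningless in either dialect and are dropped
#' (`NA`) with a warning. After conversion the result is clipped to
#' \[0.21, 1\] with a warning when clipping occurs.
#'
#' @param raw Numeric vector of raw FiO2 values; all must be positive.
#' @return Numeric vector of fractions in \[0.21, 1\] (`NA` for ambiguous
#'   inputs).
#' @export
#' @examples
#' normalize_fio2(c(40, 0.4, 1.0, 100))
normalize_fio2 <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.na(raw) & raw <= 0)) {
    stop("FiO2 must be positive", call. = FALSE)
  }
  out <- raw
  ambiguous <- !is.na(raw) & raw > 1 & raw < 21
  if (any(ambiguous)) {
    warning(sprintf("%d FiO2 value(s) in (1, 21) are ambiguous (neither fraction nor percent); dropped",
                    sum(ambiguous)), call. = FALSE)
    out[ambiguous] <- NA_real_
  }
  pct <- !is.na(out) & out > 1
  out[pct] <- out[pct] / 100
  clip <- !is.na(out) & (out < 0.21 | out > 1)
  if (any(clip)) {
    warning(sprintf("%d FiO2 value(s) clipped into [0.21, 1]", sum(clip)),
            call. = FALSE)
    out[clip] <- pmin(pmax(out[clip], 0.21), 1)
  }
  out
}

#' Filter a cohort to analyzable admissions
#'
#' Keeps adult admissions (age >= 18) that have at least one PaO2, one FiO2
#' and one PEEP observation and at least one chest-radiograph note — the
#' minimal data needed to evaluate the Berlin criteria. Each excluded
#' admission is counted under its first failing reason, checked in the order
#' age, missing PaO2, missing FiO2, missing PEEP, missing chest radiograph.
#'
#' @param admissions List of `admission_record` objects.
#' @return List with `admissions` (the kept records) and `exclusions`
#'   (named integer vector of per-reason counts).
#' @export
cohort_filter <- function(admissions) {
  reasons <- c("age", "missing PaO2", "missing FiO2", "missing PEEP",
               "missing chest radiograph")
  counts <- stats::setNames(integer(length(reasons)), reasons)
  keep <- logical(length(admissions))
  for (i in seq_along(admissions)) {
    a <- admissions[[i]]
    vars <- a$observations$variable
    reason <- if (a$age < 18) "age"
      else if (!"pao2" %in% vars) "missing PaO2"
      else if (!"fio2" %in% vars) "missing FiO2"
      else if (!"peep" %in% vars) "missing PEEP"
      else if (!"chest_radiograph" %in% a$notes$category) "missing chest radiograph"
      else NA_character_
    if (is.na(reason)) keep[i] <- TRUE else counts[reason] <- counts[reason] + 1L
  }
  list(admissions = admissions[keep], exclusions = counts)
}
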