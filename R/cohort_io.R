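#' @title Cohort readers and writers
#' @name cohort_io
#' @description
#' CSV (one table per entity) and JSON (one object per admission) readers and
#' writers for admission cohorts. Timestamps are ISO-8601 in files and are
#' converted to minutes since admission in memory. Unparseable rows are
#' skipped with a warning and counted; a missing mandatory table is an error.
NULL

.MANDATORY_TABLES <- c("admissions.csv", "observations.csv", "notes.csv")
.OPTIONAL_TABLES <- c("vent_episodes.csv", "procedures.csv", "diagnoses.csv")

# ISO-8601 parser that yields NA (never an error) for malformed input, so
# bad rows can be skipped with a warning rather than aborting the load.
parse_ts <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- NA_character_
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (f in fmts) {
    todo <- which(is.na(out) & !is.na(x))
    if (length(todo) == 0L) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

format_ts <- function(admit, minutes) {
  format(admit + minutes * 60, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

read_table_or_empty <- function(dir, file, cols) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    if (file %in% .MANDATORY_TABLES) {
      stop("missing mandatory table: ", file, call. = FALSE)
    }
    return(stats::setNames(as.data.frame(replicate(length(cols), character(0),
                                                   simplify = FALSE)), cols))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(file, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[, cols, drop = FALSE]
}

#' Load a cohort from a directory of CSV tables (or a JSON mirror)
#'
#' Expects `admissions.csv`, `observations.csv` and `notes.csv` (mandatory)
#' plus optional `vent_episodes.csv`, `procedures.csv` and `diagnoses.csv`,
#' in the documented schema. A directory containing `cohort.json` (or a path
#' to a `.json` file with one object per admission) is read through the JSON
#' mirror instead. Rows with unparseable timestamps or values are skipped
#' with a warning; duplicate observations at the same timestamp keep the
#' last-read value.
#'
#' @param path Directory containing the tables, or a `.json` cohort file.
#' @return List of `admission_record` objects. The number of skipped rows is
#'   attached as attribute `n_skipped`.
#' @export
load_cohort <- function(path) {
  if (length(path) == 1L && grepl("\\.json$", path) && file.exists(path)) {
    return(load_cohort_json(path))
  }
  if (!dir.exists(path)) stop("cohort directory not found: ", path, call. = FALSE)
  if (file.exists(file.path(path, "cohort.json"))) {
    return(load_cohort_json(file.path(path, "cohort.json")))
  }

  adm <- read_table_or_empty(path, "admissions.csv",
                             c("admission_id", "age", "admit_time",
                               "discharge_time", "disposition"))
  if (nrow(adm) == 0L) stop("no admissions found", call. = FALSE)
  obs <- read_table_or_empty(path, "observations.csv",
                             c("admission_id", "time", "variable", "value"))
  notes <- read_table_or_empty(path, "notes.csv",
                               c("admission_id", "note_id", "time", "category",
                                 "text"))
  vent <- read_table_or_empty(path, "vent_episodes.csv",
                              c("admission_id", "intubation_time",
                                "extubation_time"))
  proc <- read_table_or_empty(path, "procedures.csv",
                              c("admission_id", "time", "kind"))
  diag <- read_table_or_empty(path, "diagnoses.csv",
                              c("admission_id", "icd9_code", "is_primary"))

  n_skipped <- 0L
  records <- list()
  for (i in seq_len(nrow(adm))) {
    id <- adm$admission_id[i]
    admit <- parse_ts(adm$admit_time[i])
    disch <- parse_ts(adm$discharge_time[i])
    if (is.na(admit) || is.na(disch)) {
      warning("admission ", id, ": bad admit/discharge timestamp; skipped",
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    mins <- function(ts) as.numeric(difftime(ts, admit, units = "mins"))

    o <- obs[obs$admission_id == id, , drop = FALSE]
    ot <- parse_ts(o$time)
    ov <- suppressWarnings(as.numeric(o$value))
    bad <- is.na(ot) | is.na(ov) | !o$variable %in% .OBS_VARIABLES
    if (any(bad)) {
      warning("admission ", id, ": skipped ", sum(bad),
              " unparseable observation row(s)", call. = FALSE)
      n_skipped <- n_skipped + sum(bad)
    }
    o <- o[!bad, , drop = FALSE]; ot <- ot[!bad]; ov <- ov[!bad]
    if (any(o$variable == "fio2")) {
      fi <- o$variable == "fio2"
      norm <- normalize_fio2(ov[fi])
      drop_fi <- which(fi)[is.na(norm)]
      ov[fi] <- norm
      if (length(drop_fi) > 0L) {
        n_skipped <- n_skipped + length(drop_fi)
        keep <- setdiff(seq_len(nrow(o)), drop_fi)
        o <- o[keep, , drop = FALSE]; ot <- ot[keep]; ov <- ov[keep]
      }
    }
    odf <- data.frame(time = mins(ot), variable = o$variable, value = ov,
                      stringsAsFactors = FALSE)
    # duplicate (variable, time) pairs: keep the last-read value
    if (nrow(odf) > 1L) {
      key <- paste(odf$variable, odf$time)
      dup <- duplicated(key, fromLast = TRUE)
      if (any(dup)) {
        warning("admission ", id, ": ", sum(dup),
                " duplicate observation timestamp(s); kept last value",
                call. = FALSE)
        odf <- odf[!dup, , drop = FALSE]
      }
    }

    nt <- notes[notes$admission_id == id, , drop = FALSE]
    ntt <- parse_ts(nt$time)
    cat_map <- c(cxr = "chest_radiograph", chest_radiograph = "chest_radiograph",
                 echo = "echo")
    ncat <- unname(cat_map[nt$category])
    badn <- is.na(ntt) | is.na(ncat)
    if (any(badn)) {
      warning("admission ", id, ": skipped ", sum(badn), " bad note row(s)",
              call. = FALSE)
      n_skipped <- n_skipped + sum(badn)
    }
    ndf <- data.frame(note_id = nt$note_id[!badn], time = mins(ntt[!badn]),
                      category = ncat[!badn], text = nt$text[!badn],
                      stringsAsFactors = FALSE)

    v <- vent[vent$admission_id == id, , drop = FALSE]
    vi <- parse_ts(v$intubation_time)
    ve <- parse_ts(v$extubation_time)
    open_ep <- is.na(v$extubation_time) | v$extubation_time == ""
    badv <- is.na(vi) | (!open_ep & is.na(ve))
    if (any(badv)) {
      warning("admission ", id, ": skipped ", sum(badv),
              " bad ventilation row(s)", call. = FALSE)
      n_skipped <- n_skipped + sum(badv)
    }
    vdf <- data.frame(intubation = mins(vi[!badv]),
                      extubation = ifelse(open_ep[!badv], NA_real_,
                                          mins(ve)[!badv]))

    p <- proc[proc$admission_id == id, , drop = FALSE]
    pt <- parse_ts(p$time)
    badp <- is.na(pt)
    if (any(badp)) {
      warning("admission ", id, ": skipped ", sum(badp),
              " bad procedure row(s)", call. = FALSE)
      n_skipped <- n_skipped + sum(badp)
    }
    pdf <- data.frame(time = mins(pt[!badp]), kind = p$kind[!badp],
                      stringsAsFactors = FALSE)

    d <- diag[diag$admission_id == id, , drop = FALSE]
    idf <- data.frame(code = d$icd9_code,
                      is_primary = tolower(d$is_primary) %in% c("true", "t", "1"),
                      stringsAsFactors = FALSE)

    age <- suppressWarnings(as.numeric(adm$age[i]))
    if (is.na(age)) {
      warning("admission ", id, ": bad age; skipped", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    records[[id]] <- admission_record(
      admission_id = id, age = age, admit_time = admit,
      discharge_time = mins(disch),
      disposition = match.arg(adm$disposition[i], .DISPOSITIONS),
      icd_codes = idf, observations = odf, vent_episodes = vdf,
      procedures = pdf, notes = ndf)
  }
  if (length(records) == 0L) stop("no admissions found", call. = FALSE)
  records <- unname(records)
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Write a cohort to a directory of CSV tables
#'
#' Inverse of [load_cohort()]: writes the six-table CSV schema with ISO-8601
#' timestamps. `write_cohort()` followed by `load_cohort()` reproduces
#' structurally equal records.
#'
#' @param admissions List of `admission_record` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(admissions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- function(lst) do.call(rbind, lst)
  adm <- rows(lapply(admissions, function(a) data.frame(
    admission_id = a$admission_id, age = a$age,
    admit_time = format_ts(a$admit_time, 0),
    discharge_time = format_ts(a$admit_time, a$discharge_time),
    disposition = a$disposition, stringsAsFactors = FALSE)))
  obs <- rows(lapply(admissions, function(a) if (nrow(a$observations) == 0L) NULL
    else data.frame(
    admission_id = a$admission_id,
    time = format_ts(a$admit_time, a$observations$time),
    variable = a$observations$variable, value = a$observations$value,
    stringsAsFactors = FALSE)))
  notes <- rows(lapply(admissions, function(a) if (nrow(a$notes) == 0L) NULL
    else data.frame(
    admission_id = a$admission_id, note_id = a$notes$note_id,
    time = format_ts(a$admit_time, a$notes$time),
    category = ifelse(a$notes$category == "chest_radiograph", "cxr", "echo"),
    text = a$notes$text, stringsAsFactors = FALSE)))
  vent <- rows(lapply(admissions, function(a) if (nrow(a$vent_episodes) == 0L) NULL
    else data.frame(
    admission_id = a$admission_id,
    intubation_time = format_ts(a$admit_time, a$vent_episodes$intubation),
    extubation_time = ifelse(is.na(a$vent_episodes$extubation), "",
                             format_ts(a$admit_time, a$vent_episodes$extubation)),
    stringsAsFactors = FALSE)))
  proc <- rows(lapply(admissions, function(a) if (nrow(a$procedures) == 0L) NULL
    else data.frame(
    admission_id = a$admission_id,
    time = format_ts(a$admit_time, a$procedures$time),
    kind = a$procedures$kind, stringsAsFactors = FALSE)))
  diag <- rows(lapply(admissions, function(a) if (nrow(a$icd_codes) == 0L) NULL
    else data.frame(
    admission_id = a$admission_id, icd9_code = a$icd_codes$code,
    is_primary = a$icd_codes$is_primary, stringsAsFactors = FALSE)))

  wr <- function(df, file, cols) {
    if (is.null(df)) df <- stats::setNames(
      as.data.frame(replicate(length(cols), character(0), simplify = FALSE)),
      cols)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wr(adm, "admissions.csv", c("admission_id", "age", "admit_time",
                              "discharge_time", "disposition"))
  wr(obs, "observations.csv", c("admission_id", "time", "variable", "value"))
  wr(notes, "notes.csv", c("admission_id", "note_id", "time", "category", "text"))
  wr(vent, "vent_episodes.csv", c("admission_id", "intubation_time",
                                  "extubation_time"))
  wr(proc, "procedures.csv", c("admission_id", "time", "kind"))
  wr(diag, "diagnoses.csv", c("admission_id", "icd9_code", "is_primary"))
  invisible(dir)
}

load_cohort_json <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(objs) == 0L) stop("no admissions found", call. = FALSE)
  records <- lapply(objs, function(o) {
    admit <- parse_ts(o$admit_time)
    mins <- function(ts) as.numeric(difftime(parse_ts(ts), admit, units = "mins"))
    df_from <- function(lst, conv) {
      if (is.null(lst) || length(lst) == 0L) return(NULL)
      do.call(rbind, lapply(lst, conv))
    }
    obs <- df_from(o$observations, function(r) data.frame(
      time = mins(r$time), variable = r$variable,
      value = if (r$variable == "fio2")
        suppressWarnings(normalize_fio2(as.numeric(r$value)))
      else as.numeric(r$value),
      stringsAsFactors = FALSE))
    if (!is.null(obs)) obs <- obs[!is.na(obs$value), , drop = FALSE]
    notes <- df_from(o$notes, function(r) data.frame(
      note_id = r$note_id, time = mins(r$time),
      category = if (r$category %in% c("cxr", "chest_radiograph"))
        "chest_radiograph" else "echo",
      text = r$text, stringsAsFactors = FALSE))
    vent <- df_from(o$vent_episodes, function(r) data.frame(
      intubation = mins(r$intubation_time),
      extubation = if (is.null(r$extubation_time) || r$extubation_time == "")
        NA_real_ else mins(r$extubation_time)))
    proc <- df_from(o$procedures, function(r) data.frame(
      time = mins(r$time), kind = r$kind, stringsAsFactors = FALSE))
    icd <- df_from(o$diagnoses, function(r) data.frame(
      code = r$icd9_code, is_primary = isTRUE(r$is_primary),
      stringsAsFactors = FALSE))
    admission_record(
      admission_id = o$admission_id, age = as.numeric(o$age),
      admit_time = admit, discharge_time = mins(o$discharge_time),
      disposition = o$disposition,
      icd_codes = if (is.null(icd)) empty_icd() else icd,
      observations = if (is.null(obs)) empty_observations() else obs,
      vent_episodes = if (is.null(vent)) empty_vent() else vent,
      procedures = if (is.null(proc)) empty_procedures() else proc,
      notes = if (is.null(notes)) empty_notes() else notes)
  })
  attr(records, "n_skipped") <- 0L
  records
}
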