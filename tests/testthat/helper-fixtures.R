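# In-code fixtures shared across test files. All times are minutes since
# admission; h() and d() convert for readability.

h <- function(x) x * 60
d <- function(x) x * 1440

obs_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(time = r[[1]], variable = r[[2]], value = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

# A minimal admission satisfying the cohort filter, with overridable parts.
mk_admission <- function(id = "a1", age = 50, discharge = d(20),
                         disposition = "home",
                         observations = obs_df(list(h(1), "pao2", 95),
                                               list(h(1) - 30, "fio2", 0.21),
                                               list(h(1) - 60, "peep", 5)),
                         vent = data.frame(intubation = h(24),
                                           extubation = h(24) + h(100)),
                         procedures = NULL,
                         notes = data.frame(note_id = "n1", time = h(30),
                                            category = "chest_radiograph",
                                            text = "Bilateral infiltrates are again demonstrated.",
                                            stringsAsFactors = FALSE),
                         icd = NULL) {
  admission_record(
    admission_id = id, age = age,
    admit_time = as.POSIXct("2020-03-01 08:00:00", tz = "UTC"),
    discharge_time = discharge, disposition = disposition,
    icd_codes = if (is.null(icd)) data.frame(code = character(),
                                             is_primary = logical()) else icd,
    observations = observations,
    vent_episodes = vent,
    procedures = if (is.null(procedures))
      data.frame(time = numeric(), kind = character()) else procedures,
    notes = notes)
}

# An admission realizing the classic presentation: support from h(40),
# BI-positive radiograph at h(48), qualifying hypoxemia at h(50).
mk_classic_admission <- function(id = "c1", pf_value = 150,
                                 vent_hours = 72, disposition = "home") {
  mk_admission(
    id = id,
    observations = obs_df(
      list(h(40), "peep", 8),
      list(h(49), "peep", 10),
      list(h(50) - 30, "fio2", 0.5),
      list(h(50), "pao2", pf_value * 0.5),
      list(h(10), "fio2", 0.21),
      list(h(10), "pao2", 95)),
    vent = data.frame(intubation = h(40),
                      extubation = h(40) + h(vent_hours)),
    notes = data.frame(note_id = c("cx1", "cx2"),
                       time = c(h(48), h(90)),
                       category = "chest_radiograph",
                       text = c("Bilateral infiltrates are again demonstrated.",
                                "Interval resolution of bilateral infiltrates."),
                       stringsAsFactors = FALSE))
}

classic_evidence <- function(id = "c1", with_hffo = FALSE) {
  ev <- data.frame(admission_id = id, note_id = "cx1", time = h(48),
                   kind = "bi_pos", stringsAsFactors = FALSE)
  if (with_hffo) {
    ev <- rbind(ev, data.frame(admission_id = id, note_id = "e1",
                               time = d(2), kind = "hffo",
                               stringsAsFactors = FALSE))
  }
  ev
}

# Write a small hand-built CSV cohort for IO tests; returns the directory.
write_raw_cohort_dir <- function(dir = tempfile("cohort")) {
  dir.create(dir)
  writeLines(c(
    "admission_id,age,admit_time,discharge_time,disposition",
    "a1,50,2020-01-01T00:00:00,2020-01-11T00:00:00,home",
    "a2,70,2020-02-01T00:00:00,2020-02-15T12:00:00,expired",
    "a3,17,2020-03-01T00:00:00,2020-03-05T00:00:00,facility"),
    file.path(dir, "admissions.csv"))
  writeLines(c(
    "admission_id,time,variable,value",
    "a1,2020-01-01T06:00:00,pao2,80",
    "a1,2020-01-01T05:45:00,fio2,40",
    "a1,2020-01-01T05:30:00,peep,8",
    "a2,2020-02-01T10:00:00,pao2,60",
    "a2,2020-02-01T09:45:00,fio2,abc",
    "a2,2020-02-01T09:40:00,fio2,0.5",
    "a2,2020-02-01T09:30:00,peep,10",
    "a3,2020-03-01T04:00:00,pao2,90",
    "a3,2020-03-01T03:45:00,fio2,0.3",
    "a3,2020-03-01T03:30:00,peep,5"),
    file.path(dir, "observations.csv"))
  writeLines(c(
    "admission_id,note_id,time,category,text",
    "a1,n1,2020-01-01T07:00:00,cxr,Bilateral opacities are again demonstrated.",
    "a2,n2,2020-02-01T11:00:00,cxr,The lungs are clear.",
    "a2,n3,2020-02-02T11:00:00,echo,No evidence of CHF.",
    "a3,n4,2020-03-01T05:00:00,cxr,Right lower lobe pneumonia."),
    file.path(dir, "notes.csv"))
  writeLines(c(
    "admission_id,intubation_time,extubation_time",
    "a1,2020-01-01T05:00:00,2020-01-04T05:00:00",
    "a2,2020-02-01T09:00:00,"),
    file.path(dir, "vent_episodes.csv"))
  writeLines(c(
    "admission_id,time,kind",
    "a2,2020-02-03T09:00:00,tracheostomy"),
    file.path(dir, "procedures.csv"))
  writeLines(c(
    "admission_id,icd9_code,is_primary",
    "a1,038.9,TRUE",
    "a1,518.81,FALSE",
    "a2,428.31,TRUE"),
    file.path(dir, "diagnoses.csv"))
  dir
}
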