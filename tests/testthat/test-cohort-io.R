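test_that("load_cohort parses a raw CSV directory, skipping bad rows", {
  dir <- write_raw_cohort_dir()
  expect_warning(cohort <- load_cohort(dir), "unparseable")
  expect_length(cohort, 3)
  ids <- vapply(cohort, `[[`, "", "admission_id")
  a1 <- cohort[[match("a1", ids)]]
  # FiO2 given as percent in the file is normalized to a fraction
  expect_equal(obs_series(a1, "fio2")$value, 0.40)
  expect_equal(obs_series(a1, "pao2")$time, h(6))
  expect_equal(a1$icd_codes$code, c("0389", "51881"))
  expect_equal(a1$icd_codes$is_primary, c(TRUE, FALSE))
  a2 <- cohort[[match("a2", ids)]]
  # the "abc" FiO2 row was skipped; the good one survives
  expect_equal(nrow(obs_series(a2, "fio2")), 1)
  expect_true(is.na(a2$vent_episodes$extubation))   # open episode
  expect_equal(a2$procedures$kind, "tracheostomy")
  expect_true(attr(cohort, "n_skipped") >= 1)
})

test_that("load_cohort errors on missing mandatory table and empty input", {
  dir <- tempfile("empty")
  dir.create(dir)
  expect_error(load_cohort(dir), "admissions.csv")
  writeLines("admission_id,age,admit_time,discharge_time,disposition",
             file.path(dir, "admissions.csv"))
  writeLines("admission_id,time,variable,value",
             file.path(dir, "observations.csv"))
  writeLines("admission_id,note_id,time,category,text",
             file.path(dir, "notes.csv"))
  expect_error(load_cohort(dir), "no admissions found")
  expect_error(load_cohort(tempfile("absent")), "not found")
})

test_that("write_cohort then load_cohort reproduces the records", {
  co <- generate_cohort(generator_config(n = 8, seed = 5))
  dir <- tempfile("rt")
  write_cohort(co$admissions, dir)
  back <- load_cohort(dir)
  expect_length(back, length(co$admissions))
  ids <- vapply(back, `[[`, "", "admission_id")
  for (orig in co$admissions) {
    got <- back[[match(orig$admission_id, ids)]]
    expect_equal(got$age, orig$age)
    expect_equal(got$admit_time, orig$admit_time)
    expect_equal(got$discharge_time, orig$discharge_time)
    expect_equal(got$disposition, orig$disposition)
    expect_equal(got$observations, orig$observations)
    expect_equal(got$vent_episodes, orig$vent_episodes)
    expect_equal(got$procedures, orig$procedures)
    expect_equal(got$notes, orig$notes)
    expect_equal(got$icd_codes, orig$icd_codes)
  }
})

test_that("duplicate observation timestamps keep the last-read value", {
  dir <- tempfile("dup")
  dir.create(dir)
  writeLines(c("admission_id,age,admit_time,discharge_time,disposition",
               "a1,50,2020-01-01T00:00:00,2020-01-10T00:00:00,home"),
             file.path(dir, "admissions.csv"))
  writeLines(c("admission_id,time,variable,value",
               "a1,2020-01-01T06:00:00,peep,5",
               "a1,2020-01-01T06:00:00,peep,12"),
             file.path(dir, "observations.csv"))
  writeLines(c("admission_id,note_id,time,category,text",
               "a1,n1,2020-01-01T07:00:00,cxr,Lungs are clear."),
             file.path(dir, "notes.csv"))
  expect_warning(cohort <- load_cohort(dir), "duplicate")
  expect_equal(obs_series(cohort[[1]], "peep")$value, 12)
})

test_that("the JSON mirror loads one object per admission", {
  payload <- list(list(
    admission_id = "j1", age = 61,
    admit_time = "2020-05-01T00:00:00",
    discharge_time = "2020-05-12T00:00:00",
    disposition = "facility",
    observations = list(
      list(time = "2020-05-01T06:00:00", variable = "pao2", value = 80),
      list(time = "2020-05-01T05:45:00", variable = "fio2", value = 40),
      list(time = "2020-05-01T05:30:00", variable = "peep", value = 8)),
    notes = list(list(note_id = "n1", time = "2020-05-01T07:00:00",
                      category = "cxr", text = "Bilateral opacities.")),
    vent_episodes = list(list(intubation_time = "2020-05-01T05:00:00",
                              extubation_time = "2020-05-05T05:00:00")),
    procedures = list(),
    diagnoses = list(list(icd9_code = "518.81", is_primary = FALSE))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  cohort <- load_cohort(path)
  expect_length(cohort, 1)
  expect_equal(cohort[[1]]$admission_id, "j1")
  expect_equal(obs_series(cohort[[1]], "fio2")$value, 0.4)
  expect_equal(cohort[[1]]$icd_codes$code, "51881")
})
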