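test_that("prepare_text fuses phrases, keeps question marks, strips the rest", {
  out <- prepare_text("FINAL REPORT: pulmonary edema consistent with CHF.")
  toks <- strsplit(out, " ")[[1]]
  expect_true(all(c("finalreport", "pulmonaryedema", "consistentwith", "chf")
                  %in% toks))
  expect_equal(prepare_text(""), "")
  expect_match(prepare_text("infiltrate vs atelectasis?"), "\\?$")
  expect_equal(prepare_text("Chest 3 views <tag> obtained,   today."),
               "chest views obtained today")
})

test_that("de-identification placeholders map to generic tokens", {
  expect_equal(prepare_text("[**Doctor Last Name 107**] was notified"),
               "lastname was notified")
  expect_equal(prepare_text("Seen at [**Hospital 12**] on [**2119-4-2**]"),
               "seen at hospital on deid")
})

test_that("prepare_text is idempotent on its own output", {
  corpus <- generate_corpus("BI", n = 120, seed = 9, noise_rate = 0.2)
  once <- prepare_text(corpus$text)
  expect_equal(prepare_text(once), once)
})

test_that("split_sentences segments deterministically and honors abbreviations", {
  expect_equal(split_sentences("No effusion. Lungs clear."),
               c("No effusion.", "Lungs clear."))
  expect_equal(split_sentences("Dr. Smith notified."), "Dr. Smith notified.")
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("   "), character(0))
  expect_length(split_sentences("Value of 1.5 cm noted. Stable."), 2)
  expect_equal(split_sentences("Seen at 9 a.m. today. Improving."),
               c("Seen at 9 a.m. today.", "Improving."))
  expect_length(split_sentences("First line\n\nSecond block."), 2)
  expect_equal(split_sentences("Effusion vs atelectasis? Unchanged."),
               c("Effusion vs atelectasis?", "Unchanged."))
})

test_that("extract_hffo_documents builds 2-3 sentence context windows", {
  txt <- "Lines are unchanged. CHF is present. Lungs are low volume."
  docs <- extract_hffo_documents(txt)
  expect_equal(nrow(docs), 1)
  expect_equal(docs$text,
               "Lines are unchanged. CHF is present. Lungs are low volume.")
  # focal sentence first -> two-sentence document
  docs2 <- extract_hffo_documents("Mild CHF. Lungs are clear. Stable tubes.")
  expect_equal(docs2$text, "Mild CHF. Lungs are clear.")
  # no keyword -> no documents
  expect_equal(nrow(extract_hffo_documents("The lungs are clear. No change.")),
               0)
  # adjacent keyword sentences -> two overlapping documents
  docs3 <- extract_hffo_documents(
    "Tubes unchanged. CHF suspected. Fluid overload present. Low volumes.")
  expect_equal(docs3$focal_index, c(2L, 3L))
  expect_match(docs3$text[1], "Tubes unchanged. CHF suspected. Fluid overload")
  # case-insensitive keyword matching
  expect_equal(nrow(extract_hffo_documents("Severe lvsd seen.")), 1)
})

test_that("document count equals the number of keyword-containing sentences", {
  set.seed(21)
  for (i in 1:25) {
    n_sent <- sample(1:8, 1)
    has_kw <- runif(n_sent) < 0.4
    sents <- ifelse(has_kw,
                    sample(c("CHF is present.", "Volume overload noted.",
                             "There is systolic dysfunction."), n_sent,
                           replace = TRUE),
                    sample(c("Lungs are clear.", "Tubes unchanged.",
                             "No acute process."), n_sent, replace = TRUE))
    docs <- extract_hffo_documents(paste(sents, collapse = " "))
    expect_equal(nrow(docs), sum(has_kw))
  }
})
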