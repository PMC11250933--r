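#' @title Synthetic labeled note corpora
#' @name synthetic_text
#' @description
#' Seeded, template-based generation of labeled training units for the three
#' text-classification tasks: bilateral-infiltrate (BI) sentences from chest
#' radiographs and heart-failure/fluid-overload (HF/FO) context documents
#' from radiographs and echocardiograms. Labels are exact by construction:
#' positive BI sentences always assert involvement of both lungs with one of
#' the qualifying findings (infiltrate, opacity, consolidation, airspace
#' disease, aspiration, pneumonia); negatives are unilateral findings,
#' bilateral pleural effusions, atelectasis-only consolidation, resolution
#' phrasing or normal studies. Lexical noise applies label-preserving
#' synonym/abbreviation swaps and junk-token insertion.
NULL

.BI_FINDINGS <- c("infiltrates", "opacities", "consolidation",
                  "airspace disease", "aspiration", "pneumonia")

bi_positive_sentence <- function() {
  f <- sample(.BI_FINDINGS, 1)
  templates <- c(
    "There are diffuse bilateral %s throughout both lung fields.",
    "Bilateral %s are again demonstrated.",
    "Worsening bilateral %s compared to the prior study.",
    "Persistent %s involving the right and left lower lobes.",
    "Interval worsening of %s in both lungs.",
    "New bilateral %s concerning for a multifocal process.",
    "Improving but persistent bilateral %s.",
    "Extensive %s in both lungs consistent with pulmonary edema.")
  sprintf(sample(templates, 1), f)
}

bi_negative_sentence <- function() {
  f <- sample(.BI_FINDINGS, 1)
  templates <- c(
    "Right lower lobe %s is unchanged.",
    "Left basilar %s, likely atelectasis.",
    "There is a focal left retrocardiac opacity.",
    "Bilateral pleural effusions are present without focal %s.",
    "Interval resolution of bilateral %s.",
    "The lungs are clear without %s.",
    "No evidence of %s.",
    "Basilar consolidation attributed to atelectasis only.",
    "Right-sided %s with stable appearance.",
    "Single view of the chest demonstrates low lung volumes.")
  tpl <- sample(templates, 1)
  if (grepl("%s", tpl, fixed = TRUE)) sprintf(tpl, f) else tpl
}

.HFFO_NEUTRAL <- c(
  "Lines and tubes are in standard position.",
  "Lung volumes remain low.",
  "The cardiomediastinal silhouette is unchanged.",
  "Comparison is made to the prior study.",
  "An endotracheal tube terminates above the carina.",
  "Degenerative changes are noted in the spine.")

hffo_positive_focal <- function(source) {
  if (source == "echo") {
    templates <- c(
      "There is severe left ventricular systolic dysfunction.",
      "Findings are consistent with congestive heart failure.",
      "Moderate LVSD with global hypokinesis is seen.",
      "Diastolic dysfunction is present.",
      "The overall appearance suggests hypervolemia.",
      "Severe LVDD with elevated filling pressures.")
  } else {
    templates <- c(
      "Moderate pulmonary edema consistent with congestive heart failure.",
      "Findings are most consistent with fluid overload.",
      "Increased vascular congestion suggesting CHF.",
      "Cardiogenic edema is favored over other etiologies.",
      "Worsening volume overload with cardiomegaly.",
      "Hydrostatic edema is the most likely explanation.")
  }
  sample(templates, 1)
}

hffo_negative_focal <- function(source) {
  if (source == "echo") {
    templates <- c(
      "No evidence of systolic dysfunction.",
      "Normal left ventricular function without LVSD.",
      "CHF is not suggested by this study.",
      "No diastolic dysfunction is identified.",
      "Ejection fraction is normal, arguing against heart failure.")
  } else {
    templates <- c(
      "No evidence of CHF.",
      "Heart failure is not suspected.",
      "Interval resolution of CHF following diuresis.",
      "The degree of fluid overload has resolved.",
      "Hydrostatic edema is considered unlikely.")
  }
  sample(templates, 1)
}

hffo_document <- function(label, source) {
  focal <- if (label == "positive") hffo_positive_focal(source)
           else hffo_negative_focal(source)
  ctx <- sample(.HFFO_NEUTRAL, 2)
  if (stats::runif(1) < 0.25) {
    paste(ctx[1], focal)                      # focal sentence is last
  } else {
    paste(ctx[1], focal, ctx[2])
  }
}

.NOISE_SWAPS <- c("pneumonia" = "pna", "please" = "pls",
                  "compared" = "campared", "study" = "exam",
                  "unchanged" = "stable", "demonstrates" = "shows")

apply_lexical_noise <- function(text, noise_rate) {
  if (noise_rate <= 0) return(text)
  vapply(text, function(s) {
    tok <- strsplit(s, " ", fixed = TRUE)[[1]]
    hit <- stats::runif(length(tok)) < noise_rate
    for (i in which(hit)) {
      bare <- tolower(gsub("[^a-z]", "", tolower(tok[i])))
      if (bare %in% names(.NOISE_SWAPS)) {
        tok[i] <- sub(bare, .NOISE_SWAPS[[bare]], tok[i], ignore.case = TRUE)
      } else if (stats::runif(1) < 0.5) {
        tok[i] <- toupper(tok[i])
      } else {
        tok[i] <- paste0(tok[i], " [**2019-01-01**]")
      }
    }
    paste(tok, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

default_positive_rate <- function(task) {
  switch(task, BI = 0.395, HFFO_radiology = 0.564, HFFO_echo = 0.501)
}

#' Generate a labeled synthetic corpus
#'
#' Produces `n` labeled units for the given task with an exact positive
#' count of `round(n * positive_rate)` (positions shuffled), so the class
#' balance always matches the target to within one unit. Default positive
#' rates are the reference training-set rates: 39.5% (BI sentences), 56.4%
#' (HF/FO radiology documents) and 50.1% (HF/FO echo documents). Output is
#' deterministic for a given seed.
#'
#' @param task `"BI"`, `"HFFO_radiology"` or `"HFFO_echo"`.
#' @param n Number of units.
#' @param seed Integer seed.
#' @param positive_rate Target positive fraction (task default when `NULL`).
#' @param noise_rate Fraction of tokens perturbed by label-preserving
#'   lexical noise.
#' @return Labeled unit table (see [labeled_units()]).
#' @export
generate_corpus <- function(task = "BI", n = 500, seed = 1L,
                            positive_rate = NULL, noise_rate = 0) {
  task <- match.arg(task, .CLASSIFIER_TASKS)
  if (is.null(positive_rate)) positive_rate <- default_positive_rate(task)
  stopifnot(positive_rate >= 0, positive_rate <= 1, n >= 0)
  if (n == 0L) {
    return(labeled_units(character(0), character(0), character(0),
                         character(0)))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n_pos <- round(n * positive_rate)
  label <- sample(rep(c("positive", "negative"), c(n_pos, n - n_pos)))
  source <- if (task == "HFFO_echo") "echo" else "chest_radiograph"
  text <- vapply(label, function(lb) {
    if (task == "BI") {
      if (lb == "positive") bi_positive_sentence() else bi_negative_sentence()
    } else {
      hffo_document(lb, if (task == "HFFO_echo") "echo" else "cxr")
    }
  }, character(1), USE.NAMES = FALSE)
  text <- apply_lexical_noise(text, noise_rate)
  labeled_units(sprintf("%s_%05d", tolower(task), seq_len(n)), text, label,
                rep(source, n))
}
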