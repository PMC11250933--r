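#' @title Clinical text preparation
#' @name text_prepare
#' @description
#' Deterministic preparation of radiology/echocardiogram report text for the
#' bag-of-words classifiers: de-identification placeholder replacement,
#' lowercasing, phrase unification, fusing of common multi-word phrases into
#' unigrams, removal of tags/punctuation (question marks kept)/digits and
#' whitespace collapsing, with optional light stemming. Also a rule-based
#' sentence segmenter and the keyword-anchored context-document extractor
#' used for heart-failure/fluid-overload (HF/FO) classification.
NULL

#' Default trigger keywords for HF/FO context extraction
#'
#' The phrases that anchor heart-failure/fluid-overload context documents in
#' radiology and echocardiogram reports. Matched case-insensitively on
#' whitespace-normalized text, before punctuation/digit stripping, so
#' abbreviations such as "CHF" and "LVSD" match in any case.
#'
#' @return Character vector of keywords.
#' @export
hffo_keywords <- function() {
  c("cardiac shock", "cardiac arrest", "cardiac failure", "fluid overload",
    "volume overload", "heart failure", "chf", "hydrostatic", "cardiogenic",
    "hypervolemia", "systolic dysfunction", "diastolic dysfunction",
    "lvsd", "lvdd")
}

default_phrase_unification <- function() {
  c("pls" = "please",
    "pna" = "pneumonia",
    "campared to" = "compared to",
    "in comparison with" = "compared to",
    "cxr" = "chest radiograph",
    "chest x-ray" = "chest radiograph",
    "chest x ray" = "chest radiograph")
}

default_multiword_map <- function() {
  c("pulmonary edema" = "pulmonaryedema",
    "consistent with" = "consistentwith",
    "final report" = "finalreport",
    "compared to" = "comparedto",
    "heart failure" = "heartfailure",
    "cardiac failure" = "cardiacfailure",
    "cardiac arrest" = "cardiacarrest",
    "cardiac shock" = "cardiacshock",
    "fluid overload" = "fluidoverload",
    "volume overload" = "volumeoverload",
    "systolic dysfunction" = "systolicdysfunction",
    "diastolic dysfunction" = "diastolicdysfunction",
    "pleural effusion" = "pleuraleffusion",
    "pleural effusions" = "pleuraleffusion",
    "airspace disease" = "airspacedisease",
    "chest radiograph" = "chestradiograph",
    "right and left" = "bilateral",
    "both lungs" = "bilateral")
}

# A compact clinical stopword list; the standard-English alternative is the
# same list without the report-boilerplate terms.
default_stopwords <- function(kind = c("custom", "standard")) {
  kind <- match.arg(kind)
  base <- c("the", "a", "an", "and", "or", "of", "in", "on", "at", "to",
            "is", "are", "was", "were", "be", "been", "with", "for", "as",
            "by", "this", "that", "there", "it", "its", "has", "have", "had")
  if (kind == "standard") return(base)
  c(base, "finalreport", "impression", "indication", "comparison",
    "technique", "exam", "clip", "reason")
}

.DEID_CLASS_MAP <- list(
  c("last name", "lastname"),
  c("first name", "firstname"),
  c("name", "name"),
  c("hospital", "hospital"),
  c("location", "location"),
  c("date", "date"),
  c("telephone", "phone"),
  c("number", "deidnum")
)

replace_deid_placeholders <- function(x) {
  m <- gregexpr("\\[\\*\\*.*?\\*\\*\\]", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits) {
    vapply(hits, function(h) {
      inner <- tolower(gsub("^\\[\\*\\*|\\*\\*\\]$", "", h))
      for (cls in .DEID_CLASS_MAP) {
        if (grepl(cls[1], inner, fixed = TRUE)) return(cls[2])
      }
      tok <- gsub("[^a-z]", "", inner)
      if (nzchar(tok)) tok else "deid"
    }, character(1))
  })
  x
}

# Light rule-based suffix stripper (no stemming library is bundled); only
# used when config$stemming is TRUE.
light_stem <- function(tokens) {
  out <- tokens
  long <- nchar(out) > 5
  out[long] <- sub("(ingly|edly|fully)$", "", out[long])
  long <- nchar(out) > 4
  out[long] <- sub("(ing|ies|ied|ous)$", "", out[long])
  long <- nchar(out) > 3
  out[long] <- sub("(es|ed|ly)$", "", out[long])
  long <- nchar(out) > 3 & !grepl("(ss|us|is)$", out)
  out[long] <- sub("s$", "", out[long])
  out
}

#' Configuration of the text-classification pipeline
#'
#' Bundles every tunable choice of the report classifiers: preparation
#' options (stopword list, stemming, phrase unification, multi-word fusing),
#' the TF-IDF vectorizer parameters, the classifier-family hyperparameter
#' grid, the cross-validation fold count and the positive-class-F1
#' objective. All defaults follow the pipeline's tuned configuration: TF-IDF
#' over uni+bigrams with sublinear term frequency and a regularized linear
#' classifier.
#'
#' @param stopwords `"custom"` (clinical list, default) or `"standard"`.
#' @param stemming Apply light stemming after all other preparation steps.
#' @param phrase_unification Named character vector mapping variant phrases
#'   to canonical forms (applied on lowercased text).
#' @param multiword_map Named character vector fusing multi-word phrases to
#'   unigrams.
#' @param ngram_max Maximum n-gram order for the vectorizer (1 or 2).
#' @param min_df Minimum document frequency for a term to enter the
#'   vocabulary.
#' @param max_df_frac Maximum document-frequency fraction (terms above are
#'   dropped as boilerplate).
#' @param sublinear_tf Use `1 + log(tf)` instead of raw counts.
#' @param family Classifier family: `"glmnet"` (regularized logistic
#'   regression, default) or `"svm"` (linear support-vector machine).
#' @param grid Named list of hyperparameter vectors searched by
#'   cross-validation. For `glmnet`: `alpha`, `lambda`; for `svm`: `cost`.
#' @param cv_folds Number of stratified cross-validation folds (>= 2).
#' @param split_ratio Training fraction of the stratified train/test split
#'   (bilateral-infiltrate corpora default to 0.75, HF/FO to 0.80 at the
#'   training call sites).
#' @param hffo_aggregation Report-level aggregation for HF/FO documents:
#'   `"any"` (default) or `"majority"`.
#' @return An object of class `text_pipeline_config`.
#' @export
text_pipeline_config <- function(stopwords = c("custom", "standard"),
                                 stemming = FALSE,
                                 phrase_unification = default_phrase_unification(),
                                 multiword_map = default_multiword_map(),
                                 ngram_max = 2,
                                 min_df = 2,
                                 max_df_frac = 0.9,
                                 sublinear_tf = TRUE,
                                 family = c("glmnet", "svm"),
                                 grid = NULL,
                                 cv_folds = 5,
                                 split_ratio = 0.75,
                                 hffo_aggregation = c("any", "majority")) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "glmnet") {
      list(alpha = 0, lambda = c(1e-4, 1e-3, 1e-2))
    } else {
      list(cost = c(0.1, 1, 10))
    }
  }
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(
    stopwords = match.arg(stopwords),
    stemming = isTRUE(stemming),
    phrase_unification = phrase_unification,
    multiword_map = multiword_map,
    ngram_max = as.integer(ngram_max),
    min_df = as.integer(min_df),
    max_df_frac = max_df_frac,
    sublinear_tf = isTRUE(sublinear_tf),
    family = family,
    grid = grid,
    cv_folds = cv_folds,
    split_ratio = split_ratio,
    hffo_aggregation = match.arg(hffo_aggregation)
  ), class = "text_pipeline_config")
}

#' Canonicalize report text
#'
#' Applies, in order: de-identification placeholder replacement (`[** ... **]`
#' becomes a generic token per entity class), lowercasing, variant-phrase
#' unification, multi-word phrase fusing, removal of markup tags, removal of
#' punctuation except question marks, removal of digits, whitespace
#' collapsing, and optional light stemming. Idempotent on its own output.
#'
#' @param raw Character vector of raw text.
#' @param config A [text_pipeline_config()].
#' @return Character vector of canonical text.
#' @export
#' @examples
#' prepare_text("FINAL REPORT: pulmonary edema consistent with CHF.")
prepare_text <- function(raw, config = text_pipeline_config()) {
  x <- replace_deid_placeholders(as.character(raw))
  x <- tolower(x)
  for (variant in names(config$phrase_unification)) {
    x <- gsub(variant, config$phrase_unification[[variant]], x, fixed = TRUE)
  }
  for (phrase in names(config$multiword_map)) {
    x <- gsub(phrase, config$multiword_map[[phrase]], x, fixed = TRUE)
  }
  x <- gsub("<[^>]*>", " ", x)           # markup tags
  x <- gsub("[0-9]", " ", x)             # numbers
  x <- gsub("[^a-z? ]", " ", x)          # punctuation except '?'
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  if (config$stemming) {
    x <- vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
      paste(light_stem(tok), collapse = " ")
    }, character(1))
  }
  x
}

.ABBREVIATIONS <- c("dr.", "mr.", "mrs.", "ms.", "st.", "a.m.", "p.m.",
                    "vs.", "e.g.", "i.e.", "no.", "approx.", "pt.", "resp.")

#' Split a report into sentences
#'
#' Deterministic rule-based segmentation on sentence-final punctuation
#' (`.`, `!`, `?` followed by whitespace) and blank lines. Periods in a fixed
#' abbreviation list (e.g. "Dr.", "a.m.") and decimal numbers do not split.
#'
#' @param report_text Character scalar.
#' @return Character vector of sentences in document order (empty for empty
#'   input).
#' @export
split_sentences <- function(report_text) {
  if (length(report_text) != 1L) stop("report_text must be a single string",
                                      call. = FALSE)
  if (is.na(report_text) || !nzchar(trimws(report_text))) return(character(0))
  x <- report_text
  # protect abbreviation periods with a control-character placeholder,
  # preserving the original letter case
  for (ab in .ABBREVIATIONS) {
    segs <- strsplit(ab, ".", fixed = TRUE)[[1]]
    pat <- paste0("(?i)\\b", paste0("(", segs, ")\\.", collapse = ""))
    rep <- paste0("\\", seq_along(segs), "\x02", collapse = "")
    x <- gsub(pat, rep, x, perl = TRUE)
  }
  x <- gsub("\n{2,}", "\x01", x)                 # blank lines are boundaries
  x <- gsub("([.!?])(\\s+|$)", "\\1\x01", x)     # sentence-final punctuation
  parts <- strsplit(x, "\x01", fixed = TRUE)[[1]]
  parts <- gsub("\x02", ".", parts, fixed = TRUE)
  parts <- gsub("\\s+", " ", trimws(parts))
  parts[nzchar(parts)]
}

#' Extract keyword-anchored HF/FO context documents
#'
#' For every sentence containing at least one trigger keyword, emits the
#' document (previous sentence, focal sentence, next sentence); when the
#' focal sentence is first or last this is a two-sentence document. One
#' document per focal sentence, in document order. Keyword matching is
#' case-insensitive on whitespace-normalized text (before digit/punctuation
#' stripping), so abbreviations match in any case.
#'
#' @param report_text Character scalar.
#' @param keywords Character vector of trigger phrases; defaults to
#'   [hffo_keywords()].
#' @return Data frame with `focal_index` and `text` (one row per
#'   keyword-containing sentence; zero rows when no keyword occurs).
#' @export
extract_hffo_documents <- function(report_text, keywords = hffo_keywords()) {
  sents <- split_sentences(report_text)
  if (length(sents) == 0L) {
    return(data.frame(focal_index = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  norm <- tolower(gsub("\\s+", " ", sents))
  escaped <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(keywords))
  pat <- paste0("\\b(", paste(escaped, collapse = "|"), ")\\b")
  hits <- which(grepl(pat, norm, perl = TRUE))
  docs <- vapply(hits, function(i) {
    lo <- max(1L, i - 1L)
    hi <- min(length(sents), i + 1L)
    paste(sents[lo:hi], collapse = " ")
  }, character(1))
  data.frame(focal_index = hits, text = docs, stringsAsFactors = FALSE)
}

# Tokenize prepared text into the n-gram features used by the vectorizer.
tokenize_ngrams <- function(prepared, config) {
  stop_set <- default_stopwords(config$stopwords)
  lapply(strsplit(prepared, " ", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok) & !tok %in% stop_set]
    if (length(tok) == 0L) return(character(0))
    feats <- tok
    if (config$ngram_max >= 2L && length(tok) >= 2L) {
      feats <- c(feats, paste(tok[-length(tok)], tok[-1], sep = "_"))
    }
    feats
  })
}
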