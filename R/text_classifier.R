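#' @title Trainable report classifiers
#' @name text_classifier
#' @description
#' TF-IDF bag-of-n-grams vectorization and grid-searched linear classifiers
#' for the two evidence-extraction tasks: sentence-level detection of
#' bilateral infiltrates (BI) in chest radiographs, and document-level
#' detection of heart failure / fluid overload (HF/FO) in radiographs and
#' echocardiograms. Training uses a stratified train/test split and
#' stratified k-fold cross-validation maximizing positive-class F1.
NULL

.CLASSIFIER_TASKS <- c("BI", "HFFO_radiology", "HFFO_echo")

#' Construct a labeled training unit table
#'
#' @param unit_id Character vector of unit identifiers.
#' @param text One sentence (BI) or a 2-3-sentence context document (HF/FO)
#'   per unit.
#' @param label `"positive"` or `"negative"`.
#' @param source_category `"chest_radiograph"` or `"echo"`.
#' @return Data frame of labeled units.
#' @export
labeled_units <- function(unit_id, text, label, source_category) {
  stopifnot(all(label %in% c("positive", "negative")),
            all(source_category %in% .NOTE_CATEGORIES),
            all(nzchar(text)))
  data.frame(unit_id = as.character(unit_id), text = as.character(text),
             label = label, source_category = source_category,
             stringsAsFactors = FALSE)
}

# ---- TF-IDF vectorizer ------------------------------------------------------

fit_vectorizer_tokens <- function(toks, config) {
  df_counts <- table(unlist(lapply(toks, unique)))
  n_docs <- length(toks)
  keep <- df_counts >= config$min_df &
    df_counts <= ceiling(config$max_df_frac * n_docs)
  vocab <- sort(names(df_counts)[keep])
  if (length(vocab) == 0L) stop("empty vocabulary after df filtering",
                                call. = FALSE)
  df <- as.numeric(df_counts[vocab])
  idf <- log((1 + n_docs) / (1 + df)) + 1      # smoothed idf
  list(vocab = vocab, idf = idf, n_docs = n_docs)
}

vectorize_tokens <- function(toks, vectorizer, config) {
  vocab_index <- stats::setNames(seq_along(vectorizer$vocab), vectorizer$vocab)
  triplets <- lapply(seq_along(toks), function(i) {
    idx <- vocab_index[toks[[i]]]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tf <- table(idx)
    j <- as.integer(names(tf))
    x <- as.numeric(tf)
    if (config$sublinear_tf) x <- 1 + log(x)
    x <- x * vectorizer$idf[j]
    nrm <- sqrt(sum(x^2))
    if (nrm > 0) x <- x / nrm                  # l2 row normalization
    data.frame(i = i, j = j, x = x)
  })
  tr <- do.call(rbind, triplets)
  if (is.null(tr)) tr <- data.frame(i = integer(), j = integer(), x = numeric())
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(length(toks), length(vectorizer$vocab)))
}

text_tokens <- function(texts, config) {
  tokenize_ngrams(prepare_text(texts, config), config)
}

# ---- model fitting ----------------------------------------------------------

fit_linear_model <- function(x, y, family, params) {
  if (family == "glmnet") {
    fit <- glmnet::glmnet(x, factor(y, levels = c("negative", "positive")),
                          family = "binomial", alpha = params$alpha,
                          lambda = params$lambda, standardize = FALSE)
    list(family = "glmnet",
         intercept = as.numeric(fit$a0),
         coef = as.numeric(fit$beta))
  } else {
    fit <- e1071::svm(x = as.matrix(x),
                      y = factor(y, levels = c("negative", "positive")),
                      kernel = "linear", cost = params$cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, as.matrix(x[fit$index, , drop = FALSE])))
    # e1071 labels the decision value for the first factor level positive
    sign_flip <- if (fit$levels[1] == "negative") -1 else 1
    list(family = "svm",
         intercept = sign_flip * -fit$rho,
         coef = sign_flip * as.numeric(w))
  }
}

predict_linear_scores <- function(model, x) {
  as.numeric(x %*% model$coef) + model$intercept
}

predict_labels <- function(model, x) {
  ifelse(predict_linear_scores(model, x) > 0, "positive", "negative")
}

stratified_split <- function(labels, train_frac) {
  train <- logical(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_train <- round(length(idx) * train_frac)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

binary_metrics <- function(truth, pred) {
  tp <- sum(truth == "positive" & pred == "positive")
  fp <- sum(truth == "negative" & pred == "positive")
  fn <- sum(truth == "positive" & pred == "negative")
  tn <- sum(truth == "negative" & pred == "negative")
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_pos <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1_pos <- if (prec_pos + rec_pos > 0)
    2 * prec_pos * rec_pos / (prec_pos + rec_pos) else 0
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_neg <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1_neg <- if (prec_neg + rec_neg > 0)
    2 * prec_neg * rec_neg / (prec_neg + rec_neg) else 0
  c(accuracy = (tp + tn) / length(truth),
    precision_pos = prec_pos, recall_pos = rec_pos, f1_pos = f1_pos,
    precision_neg = prec_neg, recall_neg = rec_neg, f1_neg = f1_neg)
}

expand_param_grid <- function(grid) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

#' Train a report-evidence text classifier
#'
#' Splits the labeled units into stratified train/test sets at
#' `config$split_ratio`, grid-searches the configured hyperparameters with
#' stratified `config$cv_folds`-fold cross-validation on the training split
#' (objective: positive-class F1), refits the winning configuration on the
#' full training split, and reports held-out metrics. Deterministic for a
#' given seed.
#'
#' @param data Data frame of labeled units (see [labeled_units()]).
#' @param task One of `"BI"`, `"HFFO_radiology"`, `"HFFO_echo"`.
#' @param config A [text_pipeline_config()].
#' @param seed Integer seed controlling the split and fold assignment.
#' @return An object of class `trained_text_classifier` with the fitted
#'   vectorizer, linear weights, the winning hyperparameters, fold scores
#'   and the held-out evaluation (`$holdout`).
#' @export
train_text_classifier <- function(data, task = "BI",
                                  config = text_pipeline_config(),
                                  seed = 1L) {
  task <- match.arg(task, .CLASSIFIER_TASKS)
  if (length(unique(data$label)) < 2L) {
    stop("single class: training data must contain both positive and negative units",
         call. = FALSE)
  }
  if (nrow(data) < 10L * config$cv_folds) {
    stop("too few units: need at least 10 x cv_folds", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  train <- stratified_split(data$label, config$split_ratio)
  train_data <- data[train, , drop = FALSE]
  test_data <- data[!train, , drop = FALSE]
  folds <- stratified_folds(train_data$label, config$cv_folds)

  # tokenization is deterministic, so do it once for the whole corpus
  all_tokens <- text_tokens(data$text, config)
  train_tokens <- all_tokens[train]
  test_tokens <- all_tokens[!train]

  combos <- expand_param_grid(config$grid)
  cv_scores <- numeric(length(combos))
  fold_fits <- vector("list", config$cv_folds)
  for (k in seq_len(config$cv_folds)) {
    tr <- folds != k
    vec <- fit_vectorizer_tokens(train_tokens[tr], config)
    fold_fits[[k]] <- list(tr = tr, vec = vec,
                           xtr = vectorize_tokens(train_tokens[tr], vec, config),
                           xte = vectorize_tokens(train_tokens[!tr], vec, config))
  }
  for (ci in seq_along(combos)) {
    fold_f1 <- vapply(fold_fits, function(ff) {
      m <- fit_linear_model(ff$xtr, train_data$label[ff$tr], config$family,
                            combos[[ci]])
      binary_metrics(train_data$label[!ff$tr],
                     predict_labels(m, ff$xte))[["f1_pos"]]
    }, numeric(1))
    cv_scores[ci] <- mean(fold_f1)
  }
  best <- which.max(cv_scores)

  vectorizer <- fit_vectorizer_tokens(train_tokens, config)
  xtr <- vectorize_tokens(train_tokens, vectorizer, config)
  model <- fit_linear_model(xtr, train_data$label, config$family, combos[[best]])
  xte <- vectorize_tokens(test_tokens, vectorizer, config)
  holdout <- binary_metrics(test_data$label, predict_labels(model, xte))

  structure(list(
    task = task,
    config = config,
    vectorizer = vectorizer,
    model = model,
    best_params = combos[[best]],
    cv_scores = data.frame(combo = seq_along(combos), f1_pos = cv_scores),
    holdout = holdout,
    metadata = list(seed = seed, split_ratio = config$split_ratio,
                    n_train = nrow(train_data), n_test = nrow(test_data))
  ), class = "trained_text_classifier")
}

#' @export
print.trained_text_classifier <- function(x, ...) {
  cat(sprintf("<trained_text_classifier %s: %s, %d features>\n",
              x$task, x$model$family, length(x$vectorizer$vocab)))
  cat(sprintf("  held-out accuracy %.3f, positive-class F1 %.3f\n",
              x$holdout[["accuracy"]], x$holdout[["f1_pos"]]))
  invisible(x)
}

#' Classify texts with a trained classifier
#'
#' @param model A `trained_text_classifier`.
#' @param texts Character vector.
#' @return Data frame with `text`, `score` (linear decision value) and
#'   `label`.
#' @export
classify_texts <- function(model, texts) {
  if (length(texts) == 0L) {
    return(data.frame(text = character(), score = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  x <- vectorize_tokens(text_tokens(texts, model$config), model$vectorizer,
                        model$config)
  scores <- predict_linear_scores(model$model, x)
  data.frame(text = texts, score = scores,
             label = ifelse(scores > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Classify a clinical note at report level
#'
#' For BI the note is split into sentences and each sentence is classified;
#' the report is positive iff at least one sentence is positive. For HF/FO
#' the keyword-anchored context documents are extracted first and classified;
#' a report with no trigger keyword is negative with no units. Report-level
#' aggregation for HF/FO follows `config$hffo_aggregation` (`"any"` by
#' default, `"majority"` optional).
#'
#' @param note One-row note data frame (or list) with `category` and `text`.
#' @param model A `trained_text_classifier`; its task must be compatible with
#'   the note category (`BI` and `HFFO_radiology` apply to chest radiographs,
#'   `HFFO_echo` to echocardiograms).
#' @return List with `label` (`"positive"`/`"negative"`) and
#'   `unit_decisions` (per-sentence or per-document data frame).
#' @export
classify_report <- function(note, model) {
  expected <- switch(model$task,
                     BI = "chest_radiograph",
                     HFFO_radiology = "chest_radiograph",
                     HFFO_echo = "echo")
  if (!identical(note$category, expected)) {
    stop(sprintf("task %s cannot classify a '%s' note", model$task,
                 note$category), call. = FALSE)
  }
  if (model$task == "BI") {
    units <- split_sentences(note$text)
  } else {
    units <- extract_hffo_documents(note$text)$text
  }
  decisions <- classify_texts(model, units)
  n_pos <- sum(decisions$label == "positive")
  label <- if (model$task == "BI" || model$config$hffo_aggregation == "any") {
    if (n_pos >= 1L) "positive" else "negative"
  } else {
    if (nrow(decisions) > 0L && n_pos > nrow(decisions) / 2) "positive"
    else "negative"
  }
  list(label = label, unit_decisions = decisions)
}

#' Replicate the train/evaluate pipeline over random splits
#'
#' Reruns [train_text_classifier()] with seeds `base_seed`,
#' `base_seed + 1`, ..., `base_seed + n_reps - 1` and summarizes each
#' held-out metric as minimum, maximum and mean with a Student-t 95%
#' confidence half-width over the replicates.
#'
#' @param data Labeled unit table.
#' @param task Classifier task.
#' @param config A [text_pipeline_config()].
#' @param n_reps Number of replicates (>= 2; the reference analysis uses 30).
#' @param base_seed First seed.
#' @return List with `summary` (one row per metric: min, max, mean,
#'   ci95_halfwidth) and `replicates` (per-seed metric rows).
#' @export
replicate_evaluation <- function(data, task = "BI",
                                 config = text_pipeline_config(),
                                 n_reps = 30L, base_seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  seeds <- base_seed + seq_len(n_reps) - 1L
  reps <- do.call(rbind, lapply(seeds, function(s) {
    fit <- train_text_classifier(data, task = task, config = config, seed = s)
    c(seed = s, fit$holdout)
  }))
  reps <- as.data.frame(reps)
  metrics <- setdiff(names(reps), "seed")
  summary <- do.call(rbind, lapply(metrics, function(m) {
    v <- reps[[m]]
    half <- stats::qt(0.975, df = n_reps - 1L) * stats::sd(v) / sqrt(n_reps)
    data.frame(metric = m, min = min(v), max = max(v), mean = mean(v),
               ci95_halfwidth = half, stringsAsFactors = FALSE)
  }))
  list(summary = summary, replicates = reps)
}

#' Save a trained classifier to a single JSON archive
#'
#' Serializes the configuration snapshot, vocabulary, idf weights and linear
#' coefficients with full double precision so that a reloaded model makes
#' identical predictions.
#'
#' @param model A `trained_text_classifier`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_text_classifier <- function(model, path) {
  cfg <- unclass(model$config)
  # named atomic vectors lose their names in JSON arrays; store maps as
  # named lists instead
  cfg$phrase_unification <- as.list(cfg$phrase_unification)
  cfg$multiword_map <- as.list(cfg$multiword_map)
  payload <- list(
    format = "berlinards-text-classifier-v1",
    task = model$task,
    config = cfg,
    vocab = model$vectorizer$vocab,
    idf = model$vectorizer$idf,
    n_docs = model$vectorizer$n_docs,
    family = model$model$family,
    intercept = model$model$intercept,
    coef = model$model$coef,
    best_params = model$best_params,
    holdout = as.list(model$holdout),
    metadata = model$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a classifier saved by [save_text_classifier()]
#'
#' @param path Path to the JSON archive.
#' @return A `trained_text_classifier`.
#' @export
load_text_classifier <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "berlinards-text-classifier-v1")) {
    stop("not a berlinards classifier archive: ", path, call. = FALSE)
  }
  cfg <- p$config
  config <- text_pipeline_config(
    stopwords = cfg$stopwords, stemming = cfg$stemming,
    phrase_unification = unlist(cfg$phrase_unification),
    multiword_map = unlist(cfg$multiword_map),
    ngram_max = cfg$ngram_max, min_df = cfg$min_df,
    max_df_frac = cfg$max_df_frac, sublinear_tf = cfg$sublinear_tf,
    family = cfg$family, grid = as.list(cfg$grid), cv_folds = cfg$cv_folds,
    split_ratio = cfg$split_ratio, hffo_aggregation = cfg$hffo_aggregation)
  structure(list(
    task = p$task,
    config = config,
    vectorizer = list(vocab = p$vocab, idf = p$idf, n_docs = p$n_docs),
    model = list(family = p$family, intercept = p$intercept, coef = p$coef),
    best_params = p$best_params,
    cv_scores = NULL,
    holdout = unlist(p$holdout),
    metadata = p$metadata
  ), class = "trained_text_classifier")
}
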