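# Nested leave-one-participant-out cross-validation. The outer loop holds
# out one participant; everything label-aware -- Hamming comparator pools,
# the sparsity filter, scaler statistics, feature selection, and
# hyperparameter tuning -- is recomputed from the n-1 training rows only.
# Each fold's RNG seed derives from (base seed, held-out id), never from
# the fold's position, so a fold is exactly reproducible from its training
# rows alone (the leakage audit relies on this).

#' Cross-validation configuration
#'
#' @param seed Base RNG seed for the whole run.
#' @param inner_folds Stratified inner-CV folds for hyperparameter tuning
#'   (study default 20; automatically reduced when a class is smaller).
#' @param budget Hyperparameter configurations evaluated per model per fold
#'   (default 25); 1 = defaults only.
#' @param meta_folds Stratified folds for the stacking meta-learner's
#'   out-of-fold predictions (study default 10).
#' @return A `cv_config` list.
#' @export
cv_config <- function(seed = 1L, inner_folds = 20L, budget = 25L,
                      meta_folds = 10L) {
  structure(list(seed = as.integer(seed), inner_folds = as.integer(inner_folds),
                 budget = as.integer(budget),
                 meta_folds = as.integer(meta_folds)), class = "cv_config")
}

#' Build a feature-selection closure for the CV driver
#'
#' @param method `"ig"`, `"rf"`, `"boruta"`, or `"stable"`.
#' @param ... Passed to the selector ([ig_rank()], [embedded_rf_rank()],
#'   [boruta_select()], [stability_select()]), e.g. `k`, `max_depth`,
#'   `pi_th`, `B`.
#' @return A function `(X, y) -> selection_result`.
#' @export
fs_method <- function(method = c("ig", "rf", "boruta", "stable"), ...) {
  method <- match.arg(method)
  args <- list(...)
  fun <- switch(method, ig = ig_rank, rf = embedded_rf_rank,
                boruta = boruta_select, stable = stability_select)
  function(X, y) do.call(fun, c(list(X = X, y = y), args))
}

fold_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 1977326743
  as.integer((as.numeric(seed) * 104729 + h) %% 2147483629)
}

labels01 <- function(labels) {
  if (!all(labels %in% c("depressed", "nondepressed")))
    stop("labels must be 'depressed'/'nondepressed'")
  stats::setNames(as.integer(labels == "depressed"), names(labels))
}

stratified_folds <- function(y01, k) {
  n <- length(y01)
  kmax <- min(table(factor(y01, levels = 0:1)))
  if (k > kmax) {
    warning(sprintf("reducing fold count from %d to %d (smallest class)",
                    k, kmax))
    k <- max(2L, kmax)
  }
  fold <- integer(n)
  for (cl in unique(y01)) {
    idx <- sample(which(y01 == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

tune_model <- function(entry, X, y01, budget, inner_folds) {
  cands <- list(entry$default_params)
  if (budget > 1L)
    cands <- c(cands, replicate(budget - 1L, entry$sample_params(),
                                simplify = FALSE))
  if (length(cands) == 1L && !length(cands[[1]]))
    return(list(params = cands[[1]], f1 = NA_real_))
  fold <- stratified_folds(y01, inner_folds)
  k <- max(fold)
  f1s <- vapply(cands, function(par) {
    prob <- rep(NA_real_, length(y01))
    for (f in seq_len(k)) {
      tr <- fold != f
      # some learners need >= 2 members of each class to fit
      if (min(table(factor(y01[tr], levels = 0:1))) < 2L) next
      fit <- entry$fit(X[tr, , drop = FALSE], y01[tr], par)
      prob[!tr] <- entry$prob(fit, X[!tr, , drop = FALSE])
    }
    ok <- !is.na(prob)
    if (!any(ok)) return(NA_real_)
    eval_from_predictions(y01[ok], as.numeric(prob[ok] >= 0.5))$f1
  }, numeric(1))
  best <- if (all(is.na(f1s))) 1L else which.max(f1s)  # ties: first
  list(params = cands[[best]], f1 = f1s[best])
}

#' Fit one outer LOPOCV fold
#'
#' Recomputes Hamming features with training-fold pools, applies the
#' sparsity filter and scaler from training rows, runs the selector, tunes
#' and refits every model, and predicts the held-out participant. Exposed
#' so the leakage audit can recompute a fold from its training rows alone.
#'
#' @param fm `app_feature_matrix` containing training rows and the held-out
#'   row.
#' @param labels Named label vector for the training rows (the held-out
#'   participant's label is not consulted).
#' @param heldout Held-out participant id.
#' @param fs Selector closure from [fs_method()].
#' @param zoo Model list from [model_zoo()] (may be empty for
#'   selection-only runs).
#' @param config A [cv_config()].
#' @return A `fold_result` list.
#' @export
fold_fit <- function(fm, labels, heldout, fs, zoo, config) {
  train_ids <- setdiff(rownames(fm), heldout)
  set.seed(fold_seed(config$seed, heldout))
  lab_tr <- labels[train_ids]
  fmh <- fill_hamming(fm, lab_tr, pool = train_ids)
  fmf <- sparsity_filter(fmh, rows = train_ids)
  std <- standardize(fmf[train_ids, , drop = FALSE],
                     fmf[heldout, , drop = FALSE])
  y01 <- labels01(lab_tr)
  sel <- fs(std$train, y01)
  selected <- sel$selected
  if (!length(selected)) {  # empty set: fall back to the top-scoring feature
    selected <- names(sort(sel$scores, decreasing = TRUE))[1L]
  }
  Xtr <- std$train[, selected, drop = FALSE]
  Xte <- std$apply[, selected, drop = FALSE]
  models <- list()
  for (entry in zoo) {
    tuned <- tune_model(entry, Xtr, y01, config$budget, config$inner_folds)
    fit <- entry$fit(Xtr, y01, tuned$params)
    prob <- as.numeric(entry$prob(fit, Xte))
    models[[entry$name]] <- list(params = tuned$params,
                                 inner_f1 = tuned$f1, prob = prob,
                                 pred = as.integer(prob >= 0.5))
  }
  structure(list(heldout = heldout, selected = selected,
                 selection = sel[c("method", "config")],
                 scaler = list(center = std$center, scale = std$scale),
                 models = models, seed = fold_seed(config$seed, heldout)),
            class = "fold_result")
}

#' Nested leave-one-participant-out cross-validation
#'
#' Outer loop: each participant held out once. Inner loop: stratified
#' `inner_folds`-fold CV maximizing F1 over randomly searched
#' hyperparameter configurations. Feature selection, scaling, Hamming
#' comparator pools, and the sparsity filter all use training rows only.
#'
#' @param fm `app_feature_matrix` from [extract_features()].
#' @param labels Named `"depressed"`/`"nondepressed"` vector covering the
#'   rows of `fm`.
#' @param fs Selector closure from [fs_method()].
#' @param zoo Model list from [model_zoo()].
#' @param config A [cv_config()].
#' @return A `nested_cv` list: `reports` (per-model [metrics()]),
#'   `folds` (per-fold `fold_result`s), `predictions` (per-model matrix of
#'   held-out probabilities), plus the inputs' bookkeeping.
#' @export
nested_lopocv <- function(fm, labels, fs, zoo = model_zoo(),
                          config = cv_config()) {
  ids <- rownames(fm)
  if (!all(ids %in% names(labels))) stop("labels missing for some rows")
  y <- labels01(labels[ids])
  if (min(table(factor(y, levels = 0:1))) < 2L)
    stop("need at least 2 participants per class")
  folds <- lapply(ids, function(id)
    fold_fit(fm, labels, id, fs, zoo, config))
  names(folds) <- ids
  reports <- list()
  prob_mat <- NULL
  for (entry in zoo) {
    prob <- vapply(folds, function(f) f$models[[entry$name]]$prob,
                   numeric(1))
    pred <- as.integer(prob >= 0.5)
    reports[[entry$name]] <- eval_from_predictions(y, pred, score = prob)
    prob_mat <- cbind(prob_mat, prob)
  }
  if (!is.null(prob_mat)) colnames(prob_mat) <- names(reports)
  structure(list(reports = reports, folds = folds, predictions = prob_mat,
                 labels = labels[ids], config = config),
            class = "nested_cv")
}

#' Per-fold feature selection only (no model fitting)
#'
#' Runs the outer LOPOCV loop with an empty model zoo; useful for
#' appearance-frequency importance of a selection regime.
#'
#' @inheritParams nested_lopocv
#' @return A `nested_cv` with empty reports.
#' @export
selection_lopocv <- function(fm, labels, fs, config = cv_config()) {
  nested_lopocv(fm, labels, fs, zoo = list(), config = config)
}

#' Appearance frequency of features across LOPOCV iterations
#'
#' The percentage of outer folds whose training-fold selection included
#' each feature -- the pipeline's importance summary.
#'
#' @param result A `nested_cv` (or list of `fold_result`s).
#' @return Named numeric vector of percentages, decreasing.
#' @export
appearance_frequency <- function(result) {
  folds <- if (inherits(result, "nested_cv")) result$folds else result
  tab <- table(unlist(lapply(folds, `[[`, "selected")))
  out <- 100 * as.numeric(tab) / length(folds)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Stacking ensemble over the top-5 base classifiers
#'
#' Ranks non-baseline models by their nested-CV F1 (ties: precision, then
#' name), then rebuilds each outer fold: base learners produce stratified
#' out-of-fold predictions on the training rows (default 10-fold), a
#' logistic meta-learner is fit on those, bases are refit on all training
#' rows, and the held-out participant is predicted through the stack.
#'
#' @param result A `nested_cv` from [nested_lopocv()] (supplies per-fold
#'   selections and tuned hyperparameters).
#' @param fm,labels As in [nested_lopocv()].
#' @param zoo The zoo used for `result`.
#' @param config A [cv_config()]; `meta_folds` controls the meta-learner CV.
#' @return List with `report` (an [metrics()] report), `base_models` (the
#'   ranked top-5 names), and `predictions`.
#' @export
stack_top5 <- function(result, fm, labels, zoo = model_zoo(),
                       config = result$config) {
  cand <- setdiff(names(result$reports), "dummy")
  if (length(cand) < 5L) stop("need at least 5 evaluated base models")
  key <- vapply(cand, function(m) {
    r <- result$reports[[m]]
    sprintf("%012.9f|%012.9f", r$f1, r$precision)
  }, character(1))
  top5 <- cand[order(key, cand, decreasing = c(TRUE, FALSE),
                     method = "radix")][1:5]
  ids <- rownames(fm)
  y <- labels01(labels[ids])
  probs <- numeric(length(ids)); names(probs) <- ids
  for (id in ids) {
    f <- result$folds[[id]]
    train_ids <- setdiff(ids, id)
    set.seed((f$seed + 1L) %% 2147483629)
    lab_tr <- labels[train_ids]
    fmh <- fill_hamming(fm, lab_tr, pool = train_ids)
    fmf <- sparsity_filter(fmh, rows = train_ids)
    std <- standardize(fmf[train_ids, , drop = FALSE],
                       fmf[id, , drop = FALSE])
    Xtr <- std$train[, f$selected, drop = FALSE]
    Xte <- std$apply[, f$selected, drop = FALSE]
    ytr <- labels01(lab_tr)
    fold_assign <- stratified_folds(ytr, config$meta_folds)
    Z <- matrix(NA_real_, nrow = length(train_ids), ncol = 5L,
                dimnames = list(train_ids, top5))
    Zte <- matrix(NA_real_, nrow = 1L, ncol = 5L,
                  dimnames = list(id, top5))
    for (m in top5) {
      entry <- zoo[[m]]
      par <- f$models[[m]]$params
      for (k in seq_len(max(fold_assign))) {
        tr <- fold_assign != k
        if (length(unique(ytr[tr])) < 2L) next
        fit <- entry$fit(Xtr[tr, , drop = FALSE], ytr[tr], par)
        Z[!tr, m] <- entry$prob(fit, Xtr[!tr, , drop = FALSE])
      }
      Z[is.na(Z[, m]), m] <- mean(ytr)
      full <- entry$fit(Xtr, ytr, par)
      Zte[1L, m] <- entry$prob(full, Xte)
    }
    meta_df <- as.data.frame(Z)
    meta <- suppressWarnings(stats::glm(ytr ~ ., data = meta_df,
                                        family = stats::binomial()))
    probs[id] <- suppressWarnings(
      stats::predict(meta, newdata = as.data.frame(Zte), type = "response"))
  }
  list(report = eval_from_predictions(y, as.integer(probs >= 0.5),
                                      score = probs),
       base_models = top5, predictions = probs)
}

#' Signed per-feature attributions for a fitted model
#'
#' Model-agnostic marginal attributions: for each row and feature, the
#' change in predicted probability when that feature's value is replaced by
#' background values drawn from the data (a fast single-feature Shapley
#' surrogate). A constant model attributes 0 everywhere; a single-feature
#' model puts all mass on that feature.
#'
#' @param fit A fitted model object.
#' @param X Matrix of rows to explain.
#' @param prob Function `(fit, X) -> probability`; defaults to
#'   `predict(fit, X)`.
#' @param n_background Background draws per feature (default 20).
#' @param seed Optional RNG seed.
#' @return Matrix (rows x features) of signed attributions.
#' @export
attributions <- function(fit, X, prob = function(m, X) predict(m, X),
                         n_background = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  base_prob <- as.numeric(prob(fit, X))
  phi <- matrix(0, n, p, dimnames = dimnames(X))
  for (j in seq_len(p)) {
    bg <- X[sample.int(n, min(n_background, n), replace = n < n_background), j]
    acc <- numeric(n)
    for (b in bg) {
      Xb <- X; Xb[, j] <- b
      acc <- acc + as.numeric(prob(fit, Xb))
    }
    phi[, j] <- base_prob - acc / length(bg)
  }
  phi
}
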