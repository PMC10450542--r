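# Four feature-selection regimes. Each is a pure function of
# (X, y, config, RNG state): callers seed the RNG (the CV driver derives a
# per-fold seed), and every result carries a config snapshot.

selection_result <- function(method, selected, scores, config) {
  structure(list(method = method, selected = selected, scores = scores,
                 config = config), class = "selection_result")
}

as_label01 <- function(y) {
  if (is.character(y)) y <- factor(y, levels = c("nondepressed", "depressed"))
  as_binary01(y)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank features by information gain (filter method)
#'
#' The class label's entropy reduction given a supervised equal-frequency
#' discretization of each feature into `min(10, floor(sqrt(n)))` bins --
#' the plug-in estimator. Deterministic; ties break by column order.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Binary labels (0/1 or `"depressed"`/`"nondepressed"` factor).
#' @param k Number of top features to keep (the study swept 5..20, the
#'   lower bound from the one-in-ten rule at 51 cases).
#' @param bins Number of discretization bins; default `min(10,
#'   floor(sqrt(n)))`.
#' @return A `selection_result` with per-feature IG scores (bits).
#' @export
ig_rank <- function(X, y, k, bins = NULL) {
  X <- as.matrix(X); y01 <- as_label01(y)
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  n <- nrow(X)
  if (is.null(bins)) bins <- max(2L, min(10L, floor(sqrt(n))))
  hy <- entropy_bits(tabulate(y01 + 1L, 2L) / n)
  probs <- seq(0, 1, length.out = bins + 1)
  ig <- vapply(seq_len(ncol(X)), function(j) {
    br <- unique(stats::quantile(X[, j], probs = probs, names = FALSE))
    if (length(br) < 2L) return(0)  # constant feature
    b <- findInterval(X[, j], br, rightmost.closed = TRUE,
                      all.inside = TRUE)
    nb <- length(br) - 1L
    joint <- tabulate(b + nb * y01, nbins = 2L * nb)
    n1 <- joint[nb + seq_len(nb)]; n0 <- joint[seq_len(nb)]
    tot <- n0 + n1
    nz <- tot > 0
    p1 <- n1[nz] / tot[nz]; p0 <- n0[nz] / tot[nz]
    hterm <- -(ifelse(p1 > 0, p1 * log2(p1), 0) +
                 ifelse(p0 > 0, p0 * log2(p0), 0))
    hy - sum(tot[nz] / n * hterm)
  }, numeric(1))
  names(ig) <- colnames(X)
  ord <- order(-ig)
  selection_result("ig", colnames(X)[ord[seq_len(k)]], ig,
                   list(k = k, bins = bins))
}

#' Rank features by random-forest impurity importance (embedded method)
#'
#' @inheritParams ig_rank
#' @param ntree,max_depth Forest size/depth.
#' @return A `selection_result` with normalized importances.
#' @export
embedded_rf_rank <- function(X, y, k, ntree = 300L, max_depth = 10L) {
  X <- as.matrix(X); y01 <- as_label01(y)
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  fit <- am_forest(X, y01, ntree = ntree, max_depth = max_depth)
  imp <- fit$importance
  ord <- order(-imp)
  selection_result("rf", colnames(X)[ord[seq_len(k)]], imp,
                   list(k = k, ntree = ntree, max_depth = max_depth))
}

#' Boruta-style all-relevant feature selection (wrapper method)
#'
#' Each iteration appends a permuted "shadow" copy of every live feature,
#' fits a depth-limited random forest, and scores a hit for features whose
#' importance exceeds the best shadow importance. Hit counts are tested
#' against Binomial(iter, 1/2) with a two-step correction: Benjamini-
#' Hochberg FDR across undecided features, then a factor-2 familywise
#' correction for testing both one-sided directions. Confirmed features
#' stay; rejected features leave the design; features still tentative at
#' `max_iter` are resolved by comparing their median importance to the
#' median of the shadow maxima.
#'
#' @inheritParams ig_rank
#' @param max_depth Depth of the internal forest (the study swept 3..7).
#' @param ntree Trees per iteration.
#' @param max_iter Iteration cap.
#' @param alpha Test level (default 0.01, the reference implementation's
#'   default).
#' @param resolve_tentative Apply the rough median rule to features still
#'   tentative at `max_iter` (median importance above the median shadow
#'   maximum joins the selection), as the reference implementation does at
#'   termination. Default `TRUE`. The statistically confirmed tier is
#'   always available in `$decisions` ("confirmed"), and only that tier is
#'   expected to be empty on pure-noise input; the rough fix knowingly
#'   admits borderline features.
#' @return A `selection_result`; `scores` are hit fractions, and
#'   `$decisions` maps each feature to confirmed/rejected/tentative (as of
#'   the statistical tests, before the rough fix).
#' @export
boruta_select <- function(X, y, max_depth = 5L, ntree = 100L,
                          max_iter = 100L, alpha = 0.01,
                          resolve_tentative = TRUE) {
  X <- as.matrix(X); y01 <- as_label01(y)
  p <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- colnames(X) <- paste0("V", seq_len(p))
  status <- stats::setNames(rep("tentative", p), feat)
  hits <- stats::setNames(rep(0L, p), feat)
  imp_hist <- matrix(NA_real_, nrow = max_iter, ncol = p,
                     dimnames = list(NULL, feat))
  sha_hist <- rep(NA_real_, max_iter)
  iter <- 0L
  while (iter < max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    live <- feat[status != "rejected"]
    Xl <- X[, live, drop = FALSE]
    sh <- base::apply(Xl, 2L, sample)
    colnames(sh) <- paste0(".shadow.", live)
    # keep at least 5 shadows (as reference implementations do): with too
    # few, the shadow-max ceiling collapses and chance correlations pass
    if (ncol(sh) < 5L) {
      extra <- sample(live, 5L - ncol(sh), replace = TRUE)
      sh2 <- vapply(extra, function(f) sample(X[, f]), numeric(nrow(X)))
      colnames(sh2) <- paste0(".shadow.x", seq_along(extra))
      sh <- cbind(sh, sh2)
    }
    Xa <- cbind(Xl, sh)
    fit <- am_forest(Xa, y01, ntree = ntree, max_depth = max_depth,
                     mtry = max(1L, floor(sqrt(ncol(Xa)))),
                     oob_importance = TRUE)
    # out-of-bag permutation importance: in-sample impurity gains reward
    # chance correlations and break the all-noise null behavior
    imp <- fit$importance_oob
    shadow_max <- max(imp[colnames(sh)])
    sha_hist[iter] <- shadow_max
    imp_hist[iter, live] <- imp[live]
    hit <- live[imp[live] > shadow_max]
    hits[hit] <- hits[hit] + 1L
    und <- feat[status == "tentative"]
    if (length(und)) {
      p_acc <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[und], iter, 0.5)
      acc <- stats::p.adjust(p_acc, "BH") * 2 < alpha
      rej <- stats::p.adjust(p_rej, "BH") * 2 < alpha
      status[und[acc & !rej]] <- "confirmed"
      status[und[rej & !acc]] <- "rejected"
    }
  }
  selected <- feat[status == "confirmed"]
  und <- feat[status == "tentative"]
  if (resolve_tentative && length(und)) {  # rough median-hit resolution
    med_sha <- stats::median(sha_hist[seq_len(iter)], na.rm = TRUE)
    med_imp <- base::apply(imp_hist[seq_len(iter), und, drop = FALSE], 2L,
                           stats::median, na.rm = TRUE)
    selected <- c(selected, und[!is.na(med_imp) & med_imp > med_sha])
    selected <- feat[feat %in% selected]  # keep column order
  }
  if (!length(selected))
    warning("Boruta selected no features")
  res <- selection_result("boruta", selected, hits / max(iter, 1L),
                          list(max_depth = max_depth, ntree = ntree,
                               max_iter = max_iter, alpha = alpha,
                               resolve_tentative = resolve_tentative,
                               iters_run = iter))
  res$decisions <- status
  res
}

# Bootstrap presence frequencies of an L1-logistic base learner. The
# penalty is fixed once (internal CV on the full training fold) so that
# "selected in a subsample" means a nonzero coefficient at that penalty.
stability_frequencies <- function(X, y, B = 1000L, lambda = NULL,
                                  retry_cap = 100L) {
  X <- as.matrix(X); y01 <- as_label01(y)
  n <- nrow(X)
  if (is.null(lambda)) {
    cv <- suppressWarnings(
      glmnet::cv.glmnet(X, y01, family = "binomial", alpha = 1,
                        nfolds = 5L))
    lambda <- cv$lambda.1se
  }
  counts <- stats::setNames(rep(0L, ncol(X)), colnames(X))
  # short warm-start path ending at the fixed penalty: much cheaper than a
  # full regularization path, identical coefficients at s = lambda
  path <- lambda * 10^seq(1, 0, length.out = 6)
  for (b in seq_len(B)) {
    for (attempt in seq_len(retry_cap)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (min(tabulate(y01[idx] + 1L, 2L)) >= 2L) break
      if (attempt == retry_cap)
        stop("could not draw a two-class bootstrap subsample")
    }
    fit <- suppressWarnings(
      glmnet::glmnet(X[idx, , drop = FALSE], y01[idx],
                     family = "binomial", alpha = 1, lambda = path))
    cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))[-1L, 1L]
    counts[cf != 0] <- counts[cf != 0] + 1L
  }
  list(freq = counts / B, lambda = lambda, B = B)
}

#' Bootstrap stability selection (stable method)
#'
#' Fits an L1-penalized logistic model on `B` bootstrap subsamples (size
#' `n`, with replacement; one-class draws are redrawn) and keeps the
#' features whose presence fraction -- the share of subsamples in which the
#' coefficient is nonzero -- reaches `pi_th`.
#'
#' @inheritParams ig_rank
#' @param pi_th Presence threshold in `[0.5, 0.98]`.
#' @param B Number of bootstrap subsamples (study value 1000).
#' @param lambda Fixed L1 penalty; chosen by a 5-fold `cv.glmnet` on the
#'   full input when `NULL`.
#' @return A `selection_result` with presence fractions as scores.
#' @export
stability_select <- function(X, y, pi_th = 0.77, B = 1000L, lambda = NULL) {
  if (pi_th < 0.5 || pi_th > 0.98)
    stop("pi_th must be within [0.5, 0.98]")
  sf <- stability_frequencies(X, y, B = B, lambda = lambda)
  selected <- names(sf$freq)[sf$freq >= pi_th]
  selection_result("stable", selected, sf$freq,
                   list(pi_th = pi_th, B = sf$B, lambda = sf$lambda))
}

#' Sweep the stability-selection threshold
#'
#' Presence fractions are computed once; the sweep reads them at 0.50,
#' 0.51, ... (step 0.01) and stops after the first threshold with an empty
#' set. Set sizes are nonincreasing by construction.
#'
#' @inheritParams stability_select
#' @param from,to,by Threshold grid (defaults 0.50..0.98 by 0.01).
#' @return List with `freq` and a `data.table` `sweep` of
#'   `(pi_th, size)` plus `sets`, a named list of selected-feature vectors.
#' @export
threshold_sweep <- function(X, y, B = 1000L, lambda = NULL, from = 0.50,
                            to = 0.98, by = 0.01) {
  sf <- stability_frequencies(X, y, B = B, lambda = lambda)
  ths <- seq(from, to, by = by)
  sets <- list(); sizes <- integer(0); used <- numeric(0)
  for (t in ths) {
    sel <- names(sf$freq)[sf$freq >= t - 1e-12]
    key <- sprintf("%.2f", t)
    sets[[key]] <- sel
    sizes <- c(sizes, length(sel)); used <- c(used, t)
    if (!length(sel)) break
  }
  list(freq = sf$freq, lambda = sf$lambda,
       sweep = data.table::data.table(pi_th = used, size = sizes),
       sets = sets)
}
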