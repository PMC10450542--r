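# Classifier zoo. Every entry exposes fit(X, y01, params) -> object,
# prob(object, X) -> class-1 probability, default params, and a
# sample_params() drawing one random configuration (used by the random /
# sequential hyperparameter search). All learners that the target
# environment lacks a package for (trees, forests, boosting, linear SVM)
# run on the in-package CART engine; kNN uses FNN and the penalized
# logistic uses glmnet. The paper's three gradient-boosting variants are
# represented by the single in-package gradient-boosting machine.

zoo_entry <- function(name, fit, prob, default_params = list(),
                      sample_params = function() list()) {
  list(name = name, fit = fit, prob = prob, default_params = default_params,
       sample_params = sample_params)
}

#' The classifier zoo
#'
#' @param models Character vector choosing entries; default is the full
#'   shipped zoo: `dummy` (constant-positive baseline), `logit`, `dtree`,
#'   `rf`, `etree`, `knn`, `gnb`, `svm_linear`, `adaboost`, `gboost`.
#' @return Named list of zoo entries.
#' @export
model_zoo <- function(models = c("dummy", "logit", "dtree", "rf", "etree",
                                 "knn", "gnb", "svm_linear", "adaboost",
                                 "gboost")) {
  all <- list(
    dummy = zoo_entry(
      "dummy",
      fit = function(X, y, params) list(),
      prob = function(fit, X) rep(1, nrow(as.matrix(X)))),

    logit = zoo_entry(
      "logit",
      fit = function(X, y, params) {
        # glmnet needs >= 2 per class; degenerate folds get the prior
        if (min(table(factor(y, levels = 0:1))) < 2L)
          return(list(const = mean(y)))
        suppressWarnings(
          glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 0,
                         lambda = params$lambda))
      },
      prob = function(fit, X) {
        if (!is.null(fit$const)) return(rep(fit$const, nrow(as.matrix(X))))
        as.numeric(predict(fit, as.matrix(X), type = "response"))
      },
      default_params = list(lambda = 0.01),
      sample_params = function() list(lambda = 10^stats::runif(1, -4, 0.5))),

    dtree = zoo_entry(
      "dtree",
      fit = function(X, y, params)
        am_tree(X, y, max_depth = params$max_depth,
                min_node = params$min_node),
      prob = function(fit, X) predict(fit, X),
      default_params = list(max_depth = 5L, min_node = 2L),
      sample_params = function()
        list(max_depth = sample(2:10, 1), min_node = sample(1:5, 1))),

    rf = zoo_entry(
      "rf",
      fit = function(X, y, params)
        am_forest(X, y, ntree = params$ntree, max_depth = params$max_depth,
                  mtry = max(1L, round(params$mtry_frac * ncol(as.matrix(X))))),
      prob = function(fit, X) predict(fit, X),
      default_params = list(ntree = 100L, max_depth = 8L, mtry_frac = 0.35),
      sample_params = function()
        list(ntree = sample(c(50L, 100L, 200L), 1),
             max_depth = sample(3:12, 1),
             mtry_frac = stats::runif(1, 0.2, 0.9))),

    etree = zoo_entry(
      "etree",
      fit = function(X, y, params)
        am_forest(X, y, ntree = params$ntree, max_depth = params$max_depth,
                  mtry = max(1L, round(params$mtry_frac * ncol(as.matrix(X)))),
                  bootstrap = FALSE, random_split = TRUE),
      prob = function(fit, X) predict(fit, X),
      default_params = list(ntree = 100L, max_depth = 8L, mtry_frac = 0.6),
      sample_params = function()
        list(ntree = sample(c(50L, 100L, 200L), 1),
             max_depth = sample(3:12, 1),
             mtry_frac = stats::runif(1, 0.2, 0.9))),

    knn = zoo_entry(
      "knn",
      fit = function(X, y, params)
        list(X = as.matrix(X), y = y, k = params$k),
      prob = function(fit, X) {
        k <- min(fit$k, nrow(fit$X))
        nn <- FNN::knnx.index(fit$X, as.matrix(X), k = k)
        rowMeans(matrix(fit$y[nn], nrow = nrow(nn)))
      },
      default_params = list(k = 5L),
      sample_params = function() list(k = sample(c(3L, 5L, 7L, 9L, 11L), 1))),

    gnb = zoo_entry(
      "gnb",
      fit = function(X, y, params) {
        X <- as.matrix(X)
        eps <- params$var_smoothing * max(apply_var(X), 1e-12)
        list(
          prior1 = mean(y == 1),
          mu = lapply(0:1, function(cl) colMeans(X[y == cl, , drop = FALSE])),
          v = lapply(0:1, function(cl)
            apply_var(X[y == cl, , drop = FALSE]) + eps))
      },
      prob = function(fit, X) {
        X <- as.matrix(X)
        ll <- function(cl) {
          mu <- fit$mu[[cl + 1]]; v <- fit$v[[cl + 1]]
          rowSums(-0.5 * (sweep(X, 2, mu)^2) / rep(v, each = nrow(X)) -
                    0.5 * log(2 * pi * rep(v, each = nrow(X))))
        }
        l1 <- ll(1) + log(max(fit$prior1, 1e-12))
        l0 <- ll(0) + log(max(1 - fit$prior1, 1e-12))
        1 / (1 + exp(l0 - l1))
      },
      default_params = list(var_smoothing = 1e-9),
      sample_params = function()
        list(var_smoothing = 10^stats::runif(1, -10, -6))),

    svm_linear = zoo_entry(
      "svm_linear",
      fit = function(X, y, params) pegasos_fit(as.matrix(X), y,
                                               lambda = params$lambda,
                                               epochs = 40L),
      prob = function(fit, X)
        stats::plogis(as.matrix(X) %*% fit$w + fit$b),
      default_params = list(lambda = 0.01),
      sample_params = function() list(lambda = 10^stats::runif(1, -4, 0))),

    adaboost = zoo_entry(
      "adaboost",
      fit = function(X, y, params) adaboost_fit(as.matrix(X), y,
                                                rounds = params$rounds),
      prob = function(fit, X) adaboost_prob(fit, as.matrix(X)),
      default_params = list(rounds = 50L),
      sample_params = function()
        list(rounds = sample(c(25L, 50L, 100L), 1))),

    gboost = zoo_entry(
      "gboost",
      fit = function(X, y, params)
        gboost_fit(as.matrix(X), y, rounds = params$rounds,
                   shrinkage = params$shrinkage,
                   max_depth = params$max_depth),
      prob = function(fit, X) gboost_prob(fit, as.matrix(X)),
      default_params = list(rounds = 100L, shrinkage = 0.1, max_depth = 3L),
      sample_params = function()
        list(rounds = sample(c(50L, 100L, 200L), 1),
             shrinkage = stats::runif(1, 0.02, 0.3),
             max_depth = sample(2:5, 1)))
  )
  missing <- setdiff(models, names(all))
  if (length(missing)) stop("unknown model(s): ", paste(missing, collapse = ", "))
  all[models]
}

apply_var <- function(X) {
  n <- nrow(X)
  if (n <= 1L) return(rep(0, ncol(X)))
  colMeans(X^2) - colMeans(X)^2
}

# Pegasos-style subgradient descent for an L2-regularized linear SVM;
# scores are squashed through a logistic link for probability output.
pegasos_fit <- function(X, y, lambda = 0.01, epochs = 40L) {
  n <- nrow(X); p <- ncol(X)
  ys <- ifelse(y == 1, 1, -1)
  w <- rep(0, p); b <- 0; t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * t)
      margin <- ys[i] * (sum(w * X[i, ]) + b)
      w <- (1 - eta * lambda) * w
      if (margin < 1) {
        w <- w + eta * ys[i] * X[i, ]
        b <- b + eta * ys[i]
      }
    }
  }
  list(w = w, b = b)
}

adaboost_fit <- function(X, y, rounds = 50L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    st <- am_forest(X, y, ntree = 1L, mtry = ncol(X), max_depth = 1L,
                    min_node = 1L, bootstrap = FALSE, weights = w)
    pred <- as.numeric(predict(st, X) >= 0.5)
    err <- sum(w[pred != y])
    if (err <= 1e-12) { stumps[[m]] <- st; alphas[m] <- 10; break }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(ifelse(pred == y, -alpha, alpha))
    w <- w / sum(w)
    stumps[[m]] <- st; alphas[m] <- alpha
  }
  if (!length(stumps)) {  # degenerate: fall back to a single stump
    stumps[[1]] <- am_forest(X, y, ntree = 1L, mtry = ncol(X),
                             max_depth = 1L, bootstrap = FALSE)
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_prob <- function(fit, X) {
  f <- rep(0, nrow(X))
  for (m in seq_along(fit$stumps)) {
    pred <- 2 * as.numeric(predict(fit$stumps[[m]], X) >= 0.5) - 1
    f <- f + fit$alphas[m] * pred
  }
  stats::plogis(2 * f / max(sum(abs(fit$alphas)), 1e-12) * 3)
}

# Logistic-loss gradient boosting on regression trees over residuals.
gboost_fit <- function(X, y, rounds = 100L, shrinkage = 0.1,
                       max_depth = 3L) {
  f0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  f <- rep(f0, nrow(X))
  trees <- vector("list", rounds)
  for (m in seq_len(rounds)) {
    r <- y - stats::plogis(f)
    tr <- am_forest(X, r, ntree = 1L, mtry = ncol(X), max_depth = max_depth,
                    min_node = 2L, bootstrap = FALSE)
    f <- f + shrinkage * predict(tr, X)
    trees[[m]] <- tr
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

gboost_prob <- function(fit, X) {
  f <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) f <- f + fit$shrinkage * predict(tr, X)
  stats::plogis(f)
}
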