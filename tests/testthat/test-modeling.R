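test_that("metrics reproduces the published arithmetic", {
  # constant-positive baseline on a 51/49 cohort
  m <- metrics(tp = 51, fp = 49, tn = 0, fn = 0)
  expect_equal(round(m$precision, 3), 0.510)
  expect_equal(m$sensitivity, 1)
  expect_equal(round(m$f1, 3), 0.675)
  expect_equal(m$specificity, 0)
  # sensitivity 82.4% / specificity 71.4% -> balanced accuracy 76.9%
  m2 <- metrics(tp = 42, fn = 9, tn = 35, fp = 14)
  expect_equal(round(m2$sensitivity, 3), 0.824)
  expect_equal(round(m2$specificity, 3), 0.714)
  expect_equal(round(m2$balanced_accuracy, 3), 0.769)
  # chance: TP=FN and TN=FP
  expect_equal(metrics(10, 7, 7, 10)$balanced_accuracy, 0.5)
  expect_error(metrics(0, 0, 0, 0))
})

test_that("metric identities hold for fuzzed confusion tables", {
  set.seed(71)
  for (r in 1:200) {
    cnt <- as.list(rpois(4, 10))
    names(cnt) <- c("tp", "fp", "tn", "fn")
    if (sum(unlist(cnt)) == 0) next
    m <- do.call(metrics, cnt)
    vals <- unlist(m[c("precision", "sensitivity", "specificity", "f1",
                       "accuracy", "balanced_accuracy")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(m$f1, max(m$precision, m$sensitivity) + 1e-12)
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  }
})

test_that("roc_auc is the Mann-Whitney statistic", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(roc_auc(y, c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_true(is.na(roc_auc(c(1, 1), c(0.2, 0.3))))
})

test_that("dummy baseline reproduces prevalence arithmetic under LOPOCV", {
  set.seed(72)
  n <- 20
  y01 <- rep(c(1, 0), c(11, 9))
  X <- matrix(rnorm(n * 6), n,
              dimnames = list(sprintf("S%02d", 1:n),
                              feature_grid()$name[1:6]))
  fm <- fake_fm(X)
  labels <- label_vec(rownames(X), y01)
  res <- nested_lopocv(fm, labels, fs_method("ig", k = 3),
                       model_zoo("dummy"),
                       cv_config(seed = 1, inner_folds = 4, budget = 1))
  rep <- res$reports$dummy
  expect_equal(rep$precision, 11 / 20)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 0)
})

test_that("separable cohort: non-dummy models reach accuracy 1", {
  set.seed(73)
  n <- 24
  y01 <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 5, sd = 0.3), n)
  X[, 1] <- ifelse(y01 == 1, 3, -3) + rnorm(n, sd = 0.1)
  dimnames(X) <- list(sprintf("S%02d", 1:n), feature_grid()$name[11:15])
  fm <- fake_fm(X)
  labels <- label_vec(rownames(X), y01)
  zoo <- model_zoo(c("dummy", "logit", "dtree", "rf", "knn", "gnb",
                     "gboost"))
  res <- nested_lopocv(fm, labels, fs_method("ig", k = 2), zoo,
                       cv_config(seed = 2, inner_folds = 4, budget = 1))
  for (m in setdiff(names(res$reports), "dummy"))
    expect_equal(res$reports[[m]]$accuracy, 1)
  # stacking on perfect bases is perfect too, and beats the dummy's F1
  st <- stack_top5(res, fm, labels, zoo)
  expect_equal(st$report$accuracy, 1)
  expect_gte(st$report$f1, res$reports$dummy$f1)
  expect_length(st$base_models, 5L)
  expect_false("dummy" %in% st$base_models)
})

test_that("appearance_frequency counts fold selections", {
  folds <- list(list(selected = c("a", "b")), list(selected = c("a")),
                list(selected = c("a", "c")))
  af <- appearance_frequency(folds)
  expect_equal(unname(af["a"]), 100)
  expect_equal(unname(af["b"]), 100 / 3)
  expect_false("zzz" %in% names(af))
})

test_that("no leakage: a fold is a function of its training rows only", {
  co <- cached_cohort(n = 14)
  labels <- co$labels
  cfg <- cv_config(seed = 5, inner_folds = 3, budget = 2)
  zoo <- model_zoo(c("logit", "rf"))
  fs <- fs_method("ig", k = 4)
  heldout <- rownames(co$fm)[3]
  f1 <- fold_fit(co$fm, labels, heldout, fs, zoo, cfg)
  # recompute after deleting an unrelated row is NOT required to match;
  # recompute from the identical training set must match exactly
  f2 <- fold_fit(co$fm, labels, heldout, fs, zoo, cfg)
  expect_identical(f1, f2)
  # dropping the held-out row's data entirely (it never enters training)
  fm_wo <- extract_features(co$intervals[participant_id != heldout],
                            co$catalog, co$window,
                            participants = rownames(co$fm))
  f3 <- fold_fit(fm_wo, labels, heldout, fs, zoo, cfg)
  expect_identical(f1$selected, f3$selected)
  expect_identical(f1$scaler, f3$scaler)
  expect_identical(lapply(f1$models, `[[`, "params"),
                   lapply(f3$models, `[[`, "params"))
})

test_that("nested runs are bit-reproducible from the seed", {
  co <- cached_cohort(n = 10)
  cfg <- cv_config(seed = 9, inner_folds = 3, budget = 2)
  zoo <- model_zoo(c("dummy", "logit", "knn"))
  r1 <- nested_lopocv(co$fm, co$labels, fs_method("ig", k = 3), zoo, cfg)
  r2 <- nested_lopocv(co$fm, co$labels, fs_method("ig", k = 3), zoo, cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$reports, r2$reports)
})

test_that("attributions: constant and single-feature models", {
  set.seed(74)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  const_fit <- list()
  phi <- attributions(const_fit, X, prob = function(m, X) rep(0.7, nrow(X)),
                      seed = 1)
  expect_lt(max(abs(phi)), 1e-12)
  one_fit <- list()
  phi2 <- attributions(one_fit, X,
                       prob = function(m, X) plogis(2 * X[, "a"]), seed = 1)
  expect_lt(max(abs(phi2[, c("b", "c")])), 1e-12)
  expect_gt(mean(abs(phi2[, "a"])), 0)
  # planted-signal model: top-|attribution| feature is the signal carrier
  y <- as.numeric(X[, "a"] + 0.1 * rnorm(20) > 0)
  fit <- am_forest(X, y, ntree = 100)
  phi3 <- attributions(fit, X, seed = 2)
  expect_equal(names(which.max(colMeans(abs(phi3)))), "a")
})

test_that("inner fold count is reduced with a warning when classes are small", {
  set.seed(75)
  y01 <- rep(c(1, 0), c(3, 9))
  X <- matrix(rnorm(12 * 4), 12,
              dimnames = list(sprintf("S%02d", 1:12),
                              feature_grid()$name[21:24]))
  fm <- fake_fm(X)
  labels <- label_vec(rownames(X), y01)
  expect_warning(
    nested_lopocv(fm, labels, fs_method("ig", k = 2), model_zoo("logit"),
                  cv_config(seed = 3, inner_folds = 20, budget = 2)),
    "reducing fold count")
})
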