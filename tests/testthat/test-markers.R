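test_that("usage entropy matches the closed form", {
  expect_equal(usage_entropy(c(123)), 0)
  expect_equal(usage_entropy(numeric(0)), 0)
  expect_equal(usage_entropy(c(0, 0, 7)), 0)
  expect_equal(usage_entropy(c(5, 5)), log(2))
  expect_equal(usage_entropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(usage_entropy(c(2, 1, 1), base = 2),
               -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)))
  expect_error(usage_entropy(c(-1, 2)), "nonnegative")
})

test_that("entropy is permutation-invariant and maximal at uniform", {
  set.seed(31)
  for (r in 1:50) {
    d <- runif(sample(2:8, 1), 0, 10)
    expect_equal(usage_entropy(d), usage_entropy(sample(d)))
    expect_lte(usage_entropy(d), log(length(d)) + 1e-12)
  }
  expect_equal(usage_entropy(rep(3, 6)), log(6))
})

# Brute-force oracle for the Hamming-distance ratio
bf_ratio <- function(target, dep, nde, own = NULL, cfg = marker_config()) {
  sd_card <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  mind <- function(sets) {
    if (!is.null(own)) sets <- sets[setdiff(names(sets), own)]
    if (!length(sets)) return(NA_real_)
    min(sapply(sets, sd_card, b = target))
  }
  d <- mind(dep); nd <- mind(nde)
  if (is.na(d) || is.na(nd)) return(NA_real_)
  if (d == 0 && nd == 0) return(cfg$hamming_zero_zero)
  if (nd == 0) return(d + cfg$hamming_div_zero_offset)
  d / nd
}

test_that("hamming_ratio spec examples and conventions", {
  expect_equal(hamming_ratio(c("a", "b"), list(p1 = c("a", "b")),
                             list(p2 = "a")), 0)
  expect_equal(hamming_ratio(c("a", "b"), list(p1 = c("a", "b")),
                             list(p2 = c("a", "b"))), 1)
  expect_equal(hamming_ratio("a", list(p1 = c("b", "c")), list(p2 = "a")), 4)
  # own set excluded from its own group
  expect_true(is.na(hamming_ratio("a", list(me = "a"), list(p2 = "a"),
                                  own_id = "me")))
  # orientation flip
  cfg <- marker_config(hamming_numerator = "nondepressed")
  expect_equal(hamming_ratio(c("a"), list(p1 = c("a", "b")),
                             list(p2 = c("a", "b", "c")), config = cfg), 2)
})

test_that("hamming_ratio matches brute force on exhaustive small cohorts", {
  set.seed(41)
  universe <- letters[1:6]
  for (r in 1:300) {
    n <- sample(3:8, 1)
    sets <- lapply(seq_len(n), function(i)
      sample(universe, sample(0:6, 1)))
    names(sets) <- paste0("q", seq_len(n))
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both groups present
    dep <- sets[y == 1]; nde <- sets[y == 0]
    i <- sample(n, 1)
    expect_equal(
      hamming_ratio(sets[[i]], dep, nde, own_id = names(sets)[i]),
      bf_ratio(sets[[i]], dep, nde, own = names(sets)[i]))
  }
})

test_that("feature grid enumerates exactly 864 deterministic names", {
  g <- feature_grid()
  expect_equal(nrow(g), 864L)
  expect_equal(length(unique(g$name)), 864L)
  expect_true("Weekday_Communication_Ratio_of_Hamming_6_Hour_Mean" %in% g$name)
  expect_true("Weekend_Session_Micro_Session_Total" %in% g$name)
  expect_equal(sum(g$scope == "Session"), 24L)
  # 28 * 2 * 5 * 3 app cells
  expect_equal(sum(g$scope != "Session"), 840L)
})

test_that("extract_features hand-computed toy cohort", {
  w <- toy_window()
  cat <- toy_catalog()
  # one participant, 3 intervals in Communication on a weekday morning,
  # one crossing noon; plus a participant with zero events
  iv <- data.table::data.table(
    participant_id = "p1", package = "app.chat",
    start = c(toy_time(1, "09:00:00"), toy_time(1, "11:50:00"),
              toy_time(1, "15:00:00")),
    end = c(toy_time(1, "09:10:00"), toy_time(1, "12:10:00"),
            toy_time(1, "15:05:00")))
  iv[, duration := as.numeric(end) - as.numeric(start)]
  fm <- extract_features(iv, cat, w, participants = c("p1", "p2"))
  expect_equal(dim(fm), c(2L, 864L))
  # durations: morning 600 + 600, afternoon 600 + 300
  expect_equal(fm["p1", "Weekday_Communication_Duration_Total"], 2100)
  expect_equal(fm["p1", "Weekday_Communication_Duration_6_Hour_Mean"],
               2100 / 4)
  per <- c(0, 1200, 900, 0)
  expect_equal(fm["p1", "Weekday_Communication_Duration_6_Hour_SD"],
               sqrt(mean((per - mean(per))^2)))
  # launches attributed to the opening period: 2 morning, 1 afternoon
  expect_equal(fm["p1", "Weekday_Communication_Launch_Total"], 3)
  expect_equal(fm["p1", "Weekday_Smartphone_Launch_Total"], 3)
  # one unique app overall, in two periods for the per-period count
  expect_equal(fm["p1", "Weekday_Communication_Number_of_Apps_Total"], 1)
  expect_equal(fm["p1", "Weekday_Communication_Number_of_Apps_6_Hour_Mean"],
               2 / 4)
  # single app: zero entropy everywhere
  expect_equal(fm["p1", "Weekday_Smartphone_Entropy_Total"], 0)
  # sessions: 3 intervals, far apart -> 3 sessions, all > 60 s (engage)
  expect_equal(fm["p1", "Weekday_Session_Number_of_Sessions_Total"], 3)
  expect_equal(fm["p1", "Weekday_Session_Engage_Session_Total"], 3)
  expect_equal(fm["p1", "Weekday_Session_Review_Session_Total"], 0)
  # zero-event participant: all duration/launch/count/session cells 0
  spec <- attr(fm, "spec")
  zero_cols <- spec$measure %in% c("Duration", "Launch", "Number_of_Apps",
                                   "Entropy") | spec$scope == "Session"
  expect_true(all(fm["p2", zero_cols] == 0))
})

test_that("duration totals are conserved under diurnal splitting", {
  co <- cached_cohort(n = 8)
  fm <- co$fm
  spec <- attr(fm, "spec")
  for (day in c("Weekday", "Weekend")) {
    tot <- fm[, spec$name[spec$measure == "Duration" &
                            spec$characteristic == "Total" &
                            spec$day_type == day], drop = FALSE]
    mn <- fm[, spec$name[spec$measure == "Duration" &
                           spec$characteristic == "6_Hour_Mean" &
                           spec$day_type == day], drop = FALSE]
    expect_equal(unname(tot), unname(4 * mn), tolerance = 1e-10)
  }
  # smartphone duration equals the sum over categories
  cat_cols <- spec$name[spec$measure == "Duration" &
                          spec$characteristic == "Total" &
                          spec$day_type == "Weekday" &
                          !spec$scope %in% c("Smartphone", "Session")]
  expect_equal(unname(rowSums(fm[, cat_cols])),
               unname(fm[, "Weekday_Smartphone_Duration_Total"]),
               tolerance = 1e-8)
})

test_that("matrix-path hamming ratios agree with the set-based operation", {
  co <- cached_cohort(n = 8)
  iv <- co$intervals
  fm <- co$fm
  # reconstruct weekday communication app sets directly from intervals
  sp <- split_interval(iv)
  sp[, category := categorize(package, co$catalog)]
  lp <- launch_period(iv$start)
  la <- data.table::data.table(participant_id = iv$participant_id,
                               package = iv$package,
                               category = categorize(iv$package, co$catalog),
                               day_type = lp$day_type)
  pres <- unique(data.table::rbindlist(list(
    sp[, .(participant_id, package, category, day_type)],
    la[, .(participant_id, package, category, day_type)])))
  sets <- pres[day_type == "Weekday" & category == "Communication",
               .(apps = list(unique(package))), by = participant_id]
  all_sets <- stats::setNames(
    rep(list(character(0)), nrow(fm)), rownames(fm))
  all_sets[sets$participant_id] <- sets$apps  # absent usage = empty set
  for (id in names(all_sets)) {
    dep <- all_sets[names(all_sets) %in%
                      names(co$labels)[co$labels == "depressed"]]
    nde <- all_sets[names(all_sets) %in%
                      names(co$labels)[co$labels == "nondepressed"]]
    expect_equal(
      unname(fm[id, "Weekday_Communication_Ratio_of_Hamming_Total"]),
      hamming_ratio(all_sets[[id]], dep, nde, own_id = id))
  }
})

test_that("sparsity filter drops <50%-user categories, keeps the rest", {
  w <- toy_window()
  cat <- toy_catalog()
  # 4 participants: Education used by 2 (50%, kept), Photo by 1 (dropped)
  iv <- data.table::rbindlist(list(
    data.table::data.table(participant_id = c("a", "b", "c", "d"),
                           package = "app.chat",
                           start = toy_time(1, "10:00:00"),
                           end = toy_time(1, "10:10:00")),
    data.table::data.table(participant_id = c("a", "b"),
                           package = "app.learn",
                           start = toy_time(1, "11:00:00"),
                           end = toy_time(1, "11:10:00")),
    data.table::data.table(participant_id = "a", package = "app.cam",
                           start = toy_time(1, "12:00:00"),
                           end = toy_time(1, "12:10:00"))))
  fm <- extract_features(iv, cat, w)
  ff <- sparsity_filter(fm)
  spec <- attr(ff, "spec")
  expect_true("Education" %in% spec$scope)       # exactly 50%: retained
  expect_false("Photo and Video" %in% spec$scope)  # 25%: dropped
  expect_false("Games" %in% spec$scope)            # unused: dropped
  # smartphone and session scopes always survive
  expect_equal(sum(spec$scope == "Smartphone"), 30L)
  expect_equal(sum(spec$scope == "Session"), 24L)
  # user fractions are recomputable on a row subset
  ff2 <- sparsity_filter(fm, rows = c("a", "b"))
  expect_true("Photo and Video" %in% attr(ff2, "spec")$scope)  # 1/2 users
})

test_that("standardize uses training statistics only", {
  set.seed(51)
  tr <- matrix(rnorm(40, 5, 3), 10, dimnames = list(NULL, paste0("f", 1:4)))
  tr[, 4] <- 7  # constant column
  held <- matrix(rnorm(8, 5, 3), 2, dimnames = list(NULL, paste0("f", 1:4)))
  st <- standardize(tr, held)
  expect_equal(unname(colMeans(st$train)), rep(0, 4))
  expect_equal(unname(apply(st$train[, 1:3], 2, sd)), rep(1, 3))
  expect_equal(unname(st$train[, 4]), rep(0, 10))  # constant -> all zeros
  expect_equal(unname(st$apply[1, 2]),
               unname((held[1, 2] - mean(tr[, 2])) / sd(tr[, 2])))
  # NA cells (undefined ratios) zero-impute after scaling
  tr[3, 2] <- NA
  st2 <- standardize(tr)
  expect_equal(unname(st2$train[3, 2]), 0)
})
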