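#' Shannon entropy of an app-usage duration distribution
#'
#' `E = -sum p(j) log p(j)` with `p(j) = usage_duration(j) / sum
#' usage_duration`, taken over apps with positive duration. A single app
#' (however long it is used) gives 0; so does an empty scope, by convention.
#' Natural log by default; the base only rescales the feature and is
#' immaterial after standardization.
#'
#' @param durations Nonnegative numeric vector of per-app usage durations.
#' @param base Logarithm base (default `exp(1)`).
#' @return Entropy (nats by default).
#' @export
usage_entropy <- function(durations, base = exp(1)) {
  if (any(durations < 0)) stop("durations must be nonnegative")
  d <- durations[durations > 0]
  if (length(d) <= 1L) return(0)
  p <- d / sum(d)
  -sum(p * log(p)) / log(base)
}

#' Conventions for marker computation
#'
#' @param entropy_base Log base for [usage_entropy()].
#' @param hamming_zero_zero Value of the Hamming-distance ratio when both
#'   minimum distances are 0 (participant identical to a member of each
#'   pool); default 1 ("equally unique in both groups").
#' @param hamming_div_zero_offset When only the denominator distance is 0,
#'   the ratio is `numerator + offset` (smoothed, monotone); default 1.
#' @param hamming_numerator Which pool's minimum distance is the numerator:
#'   `"depressed"` (default) or `"nondepressed"`.
#' @return A `marker_config` list.
#' @export
marker_config <- function(entropy_base = exp(1), hamming_zero_zero = 1,
                          hamming_div_zero_offset = 1,
                          hamming_numerator = c("depressed",
                                                "nondepressed")) {
  list(entropy_base = entropy_base,
       hamming_zero_zero = hamming_zero_zero,
       hamming_div_zero_offset = hamming_div_zero_offset,
       hamming_numerator = match.arg(hamming_numerator))
}

#' Hamming-distance ratio of app-set uniqueness
#'
#' The distance between two participants is the symmetric-difference
#' cardinality of their app sets (equivalently, the Hamming distance of the
#' binary membership vectors over a fixed app universe). `D` is the minimum
#' distance from the target to the depressed pool and `ND` to the
#' nondepressed pool; the target's own set is excluded from whichever pool
#' contains it. The ratio is `D / ND` with the degenerate conventions of
#' [marker_config()]; a pool with no eligible comparator gives `NA`
#' (zero-imputed after standardization downstream).
#'
#' @param target_set Character vector (the target participant's app set).
#' @param depressed_sets,nondepressed_sets Lists of character vectors; names
#'   are participant ids.
#' @param own_id Id of the target, excluded from its own pool.
#' @param config A [marker_config()].
#' @return The ratio (numeric scalar, possibly `NA`).
#' @export
hamming_ratio <- function(target_set, depressed_sets, nondepressed_sets,
                          own_id = NULL, config = marker_config()) {
  drop_own <- function(sets) {
    if (!is.null(own_id) && !is.null(names(sets)))
      sets[names(sets) != own_id] else sets
  }
  setdist <- function(a, b) length(union(a, b)) - length(intersect(a, b))
  min_dist <- function(sets) {
    sets <- drop_own(sets)
    if (!length(sets)) return(NA_real_)
    min(vapply(sets, setdist, numeric(1), a = unique(target_set)))
  }
  d <- min_dist(depressed_sets)
  nd <- min_dist(nondepressed_sets)
  if (config$hamming_numerator == "nondepressed") { tmp <- d; d <- nd; nd <- tmp }
  ratio_convention(d, nd, config)
}

ratio_convention <- function(num, den, config) {
  out <- num / den
  both0 <- !is.na(num) & !is.na(den) & num == 0 & den == 0
  out[both0] <- config$hamming_zero_zero
  div0 <- !is.na(num) & !is.na(den) & den == 0 & num > 0
  out[div0] <- num[div0] + config$hamming_div_zero_offset
  out[is.na(num) | is.na(den)] <- NA_real_
  out
}

#' Enumerate the behavioral-marker feature grid
#'
#' 28 app scopes (27 categories + whole-smartphone) x 2 day-types x 5 core
#' measures x 3 characteristics, plus the session block (2 day-types x 4
#' session measures x 3 characteristics): exactly 864 named features. Names
#' follow `{DayType}_{Scope}_{Measure}_{Characteristic}` with
#' characteristics `Total`, `6_Hour_Mean`, `6_Hour_SD`.
#'
#' @return `data.table` with columns `name, scope, day_type, measure,
#'   characteristic`, 864 rows in canonical column order.
#' @export
feature_grid <- function() {
  days <- c("Weekday", "Weekend")
  chars <- c("Total", "6_Hour_Mean", "6_Hour_SD")
  app_scopes <- c(app_categories(), "Smartphone")
  app_measures <- c("Duration", "Launch", "Number_of_Apps", "Entropy",
                    "Ratio_of_Hamming")
  ses_measures <- c("Number_of_Sessions", "Micro_Session", "Review_Session",
                    "Engage_Session")
  g1 <- data.table::CJ(scope = app_scopes, day_type = days,
                       measure = app_measures, characteristic = chars,
                       sorted = FALSE)
  g2 <- data.table::CJ(scope = "Session", day_type = days,
                       measure = ses_measures, characteristic = chars,
                       sorted = FALSE)
  g <- data.table::rbindlist(list(g1, g2))
  g[, name := paste(day_type, gsub(" ", "_", scope), measure, characteristic,
                    sep = "_")]
  data.table::setcolorder(g, c("name", "scope", "day_type", "measure",
                               "characteristic"))
  g[]
}

p4_matrix <- function(dt, participants, value_col = "value") {
  m <- matrix(0, nrow = length(participants), ncol = 4L,
              dimnames = list(participants, diurnal_periods()))
  if (nrow(dt)) {
    dt <- dt[participant_id %in% participants]
    m[cbind(match(dt$participant_id, participants),
            match(dt$period, diurnal_periods()))] <- dt[[value_col]]
  }
  m
}

row_diurnal <- function(m4) {
  mu <- rowMeans(m4)
  list(mean = mu, sd = sqrt(rowMeans((m4 - mu)^2)))
}

# Pairwise symmetric-difference distances from a presence table
# (participant_id, package): D_ij = |AP_i xor AP_j| over the observed
# universe. Returns an n x n matrix in `participants` order.
pairwise_setdist <- function(pres, participants) {
  n <- length(participants)
  if (!nrow(pres)) return(matrix(0, n, n,
                                 dimnames = list(participants, participants)))
  pres <- unique(pres[participant_id %in% participants,
                      .(participant_id, package)])
  pkgs <- sort(unique(pres$package))
  M <- matrix(0L, n, length(pkgs), dimnames = list(participants, pkgs))
  M[cbind(match(pres$participant_id, participants),
          match(pres$package, pkgs))] <- 1L
  k <- rowSums(M)
  D <- outer(k, k, `+`) - 2 * tcrossprod(M)
  dimnames(D) <- list(participants, participants)
  D
}

# Minimum distance of every participant to a labelled pool, excluding self.
min_dist_to_pool <- function(D, pool_ids) {
  ids <- rownames(D)
  if (!length(pool_ids))
    return(stats::setNames(rep(NA_real_, length(ids)), ids))
  cols <- match(pool_ids, colnames(D))
  self <- match(ids, colnames(D))  # own column, skipped when in the pool
  self[!(ids %in% pool_ids)] <- 0L
  out <- cpp_rowmin_pool(D, cols, self)
  stats::setNames(out, ids)
}

#' Extract the full 864-cell feature matrix for a cohort
#'
#' Runs diurnal splitting, launch attribution, session segmentation, and the
#' per-scope measures over paired usage intervals. Absent usage contributes
#' 0 to counts, durations, and entropy; Hamming-ratio cells are `NA` when no
#' labels are supplied (or a comparator pool is empty) and are recomputed
#' per training fold during cross-validation.
#'
#' @param intervals Output of [pair_intervals()].
#' @param catalog An [app_catalog()].
#' @param window The [obs_window()] the intervals were clipped to (supplies
#'   the weekend definition).
#' @param labels Optional named character vector (participant id ->
#'   `"depressed"`/`"nondepressed"`) used only for the Hamming comparator
#'   pools.
#' @param participants Cohort ids; defaults to ids seen in `intervals` plus
#'   names of `labels`. Participants with no events get all-zero rows.
#' @param gap_threshold Session gap threshold in seconds (default 45).
#' @param config A [marker_config()].
#' @return An `app_feature_matrix`: numeric matrix (participants x 864) with
#'   attributes `spec` (the [feature_grid()]), `category_users` (logical
#'   participant x category usage indicators for the sparsity filter),
#'   `hamming_dist` (per scope/day/slot distance matrices for fold-wise
#'   recomputation), and `config`.
#' @export
extract_features <- function(intervals, catalog, window, labels = NULL,
                             participants = NULL, gap_threshold = 45,
                             config = marker_config()) {
  wd <- window$weekend_days
  iv <- data.table::as.data.table(intervals)
  if (is.null(participants))
    participants <- sort(unique(c(iv$participant_id, names(labels))))
  participants <- as.character(participants)
  n <- length(participants)
  grid <- feature_grid()
  X <- matrix(0, nrow = n, ncol = nrow(grid),
              dimnames = list(participants, grid$name))
  X[, grid$measure == "Ratio_of_Hamming"] <- NA_real_  # until pools known

  has_rows <- nrow(iv) > 0L
  if (has_rows) {
    iv[, category := categorize(package, catalog)]
    spl <- split_interval(iv, weekend_days = wd)
    spl <- spl[, .(dur = sum(duration)),
               by = .(participant_id, package, category, day_type, period)]
    lp <- launch_period(iv$start, weekend_days = wd)
    lau <- data.table::data.table(participant_id = iv$participant_id,
                                  package = iv$package,
                                  category = iv$category,
                                  day_type = lp$day_type, period = lp$period)
    lau <- lau[, .(nlaunch = .N),
               by = .(participant_id, package, category, day_type, period)]
    pres <- unique(data.table::rbindlist(list(
      spl[, .(participant_id, package, category, day_type, period)],
      lau[, .(participant_id, package, category, day_type, period)])))
    ses <- segment_sessions(iv, gap_threshold = gap_threshold)
    sc <- session_counts(ses, weekend_days = wd)
  } else {
    spl <- data.table::data.table(participant_id = character(),
                                  package = character(), category = character(),
                                  day_type = character(), period = character(),
                                  dur = numeric())
    lau <- data.table::data.table(participant_id = character(),
                                  package = character(), category = character(),
                                  day_type = character(), period = character(),
                                  nlaunch = integer())
    pres <- spl[, .(participant_id, package, category, day_type, period)]
    sc <- session_counts(segment_sessions(iv), weekend_days = wd)
  }

  ham_dist <- list()

  for (scope in c(app_categories(), "Smartphone")) {
    sname <- gsub(" ", "_", scope)
    in_scope <- if (scope == "Smartphone") rep(TRUE, nrow(spl))
                else spl$category == scope
    in_scope_l <- if (scope == "Smartphone") rep(TRUE, nrow(lau))
                  else lau$category == scope
    in_scope_p <- if (scope == "Smartphone") rep(TRUE, nrow(pres))
                  else pres$category == scope
    for (day in c("Weekday", "Weekend")) {
      sdt <- spl[in_scope & day_type == day]
      ldt <- lau[in_scope_l & day_type == day]
      pdt <- pres[in_scope_p & day_type == day]
      pre <- paste0(day, "_", sname, "_")

      # Duration
      dper <- sdt[, .(value = sum(dur)), by = .(participant_id, period)]
      m4 <- p4_matrix(dper, participants)
      ds <- row_diurnal(m4)
      X[, paste0(pre, "Duration_Total")] <- rowSums(m4)
      X[, paste0(pre, "Duration_6_Hour_Mean")] <- ds$mean
      X[, paste0(pre, "Duration_6_Hour_SD")] <- ds$sd

      # Launch
      lper <- ldt[, .(value = sum(nlaunch)), by = .(participant_id, period)]
      m4 <- p4_matrix(lper, participants)
      ds <- row_diurnal(m4)
      X[, paste0(pre, "Launch_Total")] <- rowSums(m4)
      X[, paste0(pre, "Launch_6_Hour_Mean")] <- ds$mean
      X[, paste0(pre, "Launch_6_Hour_SD")] <- ds$sd

      # Number of unique apps: whole day-type for Total; per period for
      # mean/SD (an app active in two periods counts in both)
      napp_tot <- pdt[, .(value = data.table::uniqueN(package)),
                      by = participant_id]
      vt <- stats::setNames(rep(0, n), participants)
      if (nrow(napp_tot)) vt[napp_tot$participant_id] <- napp_tot$value
      X[, paste0(pre, "Number_of_Apps_Total")] <- vt
      napp_per <- pdt[, .(value = data.table::uniqueN(package)),
                      by = .(participant_id, period)]
      m4 <- p4_matrix(napp_per, participants)
      ds <- row_diurnal(m4)
      X[, paste0(pre, "Number_of_Apps_6_Hour_Mean")] <- ds$mean
      X[, paste0(pre, "Number_of_Apps_6_Hour_SD")] <- ds$sd

      # Entropy over per-app durations
      ent_tot <- sdt[, .(dur = sum(dur)), by = .(participant_id, package)][
        , .(value = usage_entropy(dur, base = config$entropy_base)),
        by = participant_id]
      vt <- stats::setNames(rep(0, n), participants)
      if (nrow(ent_tot)) vt[ent_tot$participant_id] <- ent_tot$value
      X[, paste0(pre, "Entropy_Total")] <- vt
      ent_per <- sdt[, .(value = usage_entropy(dur,
                                               base = config$entropy_base)),
                     by = .(participant_id, period)]
      m4 <- p4_matrix(ent_per, participants)
      ds <- row_diurnal(m4)
      X[, paste0(pre, "Entropy_6_Hour_Mean")] <- ds$mean
      X[, paste0(pre, "Entropy_6_Hour_SD")] <- ds$sd

      # Hamming distances: store per-slot matrices; ratios filled below
      slots <- list(Total = pdt)
      for (p in diurnal_periods()) slots[[p]] <- pdt[period == p]
      ham_dist[[paste(scope, day, sep = "|")]] <-
        lapply(slots, pairwise_setdist, participants = participants)
    }
  }

  # Session block
  ses_measures <- c(Number_of_Sessions = "total", Micro_Session = "micro",
                    Review_Session = "review", Engage_Session = "engage")
  for (day in c("Weekday", "Weekend")) {
    scd <- sc[day_type == day]
    for (mname in names(ses_measures)) {
      cnt_col <- ses_measures[[mname]]
      m4 <- p4_matrix(scd[, .(participant_id, period,
                              value = get(cnt_col))], participants)
      ds <- row_diurnal(m4)
      pre <- paste0(day, "_Session_", mname, "_")
      X[, paste0(pre, "Total")] <- rowSums(m4)
      X[, paste0(pre, "6_Hour_Mean")] <- ds$mean
      X[, paste0(pre, "6_Hour_SD")] <- ds$sd
    }
  }

  # Category-user indicators (whole-week duration > 0) for the sparsity rule
  cu <- matrix(FALSE, n, length(app_categories()),
               dimnames = list(participants, app_categories()))
  if (nrow(spl)) {
    used <- spl[dur > 0, .(participant_id, category)]
    used <- unique(used)
    cu[cbind(match(used$participant_id, participants),
             match(used$category, app_categories()))] <- TRUE
  }

  fm <- X
  attr(fm, "spec") <- grid
  attr(fm, "category_users") <- cu
  attr(fm, "hamming_dist") <- ham_dist
  attr(fm, "config") <- config
  class(fm) <- c("app_feature_matrix", class(X))
  if (!is.null(labels)) fm <- fill_hamming(fm, labels)
  fm
}

#' Fill or recompute Hamming-ratio features from comparator pools
#'
#' Ratios for every participant are computed against the labelled pool
#' restricted to `pool` (e.g. a training fold); each pool member is excluded
#' from its own group. Cells stay `NA` when a group has no eligible
#' comparator.
#'
#' @param fm An `app_feature_matrix` from [extract_features()].
#' @param labels Named character vector for (at least) the pool ids.
#' @param pool Ids forming the comparator pools; default all labelled ids.
#' @return The matrix with Hamming-ratio columns (re)filled.
#' @export
fill_hamming <- function(fm, labels, pool = names(labels)) {
  config <- attr(fm, "config")
  ham <- attr(fm, "hamming_dist")
  parts <- rownames(fm)
  dep_pool <- intersect(pool, names(labels)[labels == "depressed"])
  nde_pool <- intersect(pool, names(labels)[labels == "nondepressed"])
  for (scope in c(app_categories(), "Smartphone")) {
    sname <- gsub(" ", "_", scope)
    for (day in c("Weekday", "Weekend")) {
      Ds <- ham[[paste(scope, day, sep = "|")]]
      if (is.null(Ds)) next  # matrices absent (e.g. reduced test fixtures)
      ratio_of <- function(D) {
        d <- min_dist_to_pool(D, dep_pool)
        nd <- min_dist_to_pool(D, nde_pool)
        if (config$hamming_numerator == "nondepressed") { t <- d; d <- nd; nd <- t }
        ratio_convention(d, nd, config)
      }
      pre <- paste0(day, "_", sname, "_Ratio_of_Hamming_")
      fm[, paste0(pre, "Total")] <- ratio_of(Ds$Total)
      per <- vapply(diurnal_periods(), function(p) ratio_of(Ds[[p]]),
                    numeric(length(parts)))
      mu <- rowMeans(per)
      fm[, paste0(pre, "6_Hour_Mean")] <- mu
      fm[, paste0(pre, "6_Hour_SD")] <- sqrt(rowMeans((per - mu)^2))
    }
  }
  fm
}

#' Drop features of sparsely used app categories
#'
#' A participant is a "user" of a category when their whole-week duration in
#' it is positive. Every feature of a category whose user fraction is
#' strictly below `min_user_frac` is dropped; whole-smartphone and session
#' features are always retained.
#'
#' @param fm An `app_feature_matrix`.
#' @param min_user_frac Threshold (default 0.5, strict `<` drops).
#' @param rows Participant ids over which to compute user fractions
#'   (training fold in cross-validation); default all rows.
#' @return The filtered matrix (attributes preserved; `spec` subset).
#' @export
sparsity_filter <- function(fm, min_user_frac = 0.5, rows = rownames(fm)) {
  cu <- attr(fm, "category_users")[rows, , drop = FALSE]
  frac <- colMeans(cu)
  drop_cats <- names(frac)[frac < min_user_frac]
  spec <- attr(fm, "spec")
  keep <- !(spec$scope %in% drop_cats)
  out <- fm[, keep, drop = FALSE]
  for (a in c("category_users", "hamming_dist", "config"))
    attr(out, a) <- attr(fm, a)
  attr(out, "spec") <- spec[keep]
  attr(out, "user_frac") <- frac
  class(out) <- class(fm)
  out
}

#' Standardize features with training-fold statistics
#'
#' Per-feature centering/scaling uses the training rows only (no leakage);
#' zero-variance features map to 0, and `NA` cells (undefined Hamming
#' ratios) are zero-imputed after scaling, i.e. set to the training mean.
#'
#' @param train Numeric matrix of training rows.
#' @param apply Optional matrix with the same columns to transform with the
#'   training statistics.
#' @return List with `train`, `apply` (or `NULL`), `center`, `scale`.
#' @export
standardize <- function(train, apply = NULL) {
  train <- as.matrix(train)
  center <- colMeans(train, na.rm = TRUE)
  center[is.nan(center)] <- 0
  scale <- vapply(seq_len(ncol(train)),
                  function(j) stats::sd(train[, j], na.rm = TRUE),
                  numeric(1))
  names(scale) <- colnames(train)
  scale[is.na(scale) | scale == 0] <- Inf  # constant columns -> 0
  tr <- sweep(sweep(train, 2L, center, `-`), 2L, scale, `/`)
  tr[is.na(tr)] <- 0
  ap <- NULL
  if (!is.null(apply)) {
    ap <- sweep(sweep(as.matrix(apply), 2L, center, `-`), 2L, scale, `/`)
    ap[is.na(ap)] <- 0
  }
  scale_out <- ifelse(is.infinite(scale), 0, scale)
  list(train = tr, apply = ap, center = center, scale = scale_out)
}
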