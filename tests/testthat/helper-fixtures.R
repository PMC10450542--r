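# Shared fixtures, built in code. The toy window starts Monday 2020-08-03
# 00:00 with the default Friday/Saturday weekend.

toy_window <- function() obs_window("2020-08-03")

toy_time <- function(day = 1, hms = "10:00:00") {
  as.POSIXct(sprintf("2020-08-%02d %s", 2 + day, hms), tz = "UTC")
}

make_events <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(participant_id = r[[1]],
                           timestamp = r[[2]], package = r[[3]],
                           kind = r[[4]])))
}

toy_catalog <- function() {
  app_catalog(c("app.chat", "app.feed", "app.cam", "app.learn", "app.misc"),
              c("Communication", "Social", "Photo and Video", "Education",
                "Tools"))
}

# Write an events data.table to a temp CSV in the on-disk schema.
events_csv <- function(ev) {
  f <- tempfile(fileext = ".csv")
  ev2 <- data.table::copy(ev)
  ev2[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%OS3")]
  data.table::fwrite(ev2, f)
  f
}

# A feature-matrix stand-in with the attributes the CV machinery expects:
# n rows, columns drawn from the real grid, no Hamming matrices (skipped),
# every category marked as used.
fake_fm <- function(X, feature_names = colnames(X)) {
  grid <- feature_grid()
  stopifnot(all(feature_names %in% grid$name))
  colnames(X) <- feature_names
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  attr(X, "spec") <- grid[match(feature_names, grid$name)]
  attr(X, "category_users") <- matrix(
    TRUE, nrow(X), length(app_categories()),
    dimnames = list(rownames(X), app_categories()))
  attr(X, "hamming_dist") <- list()
  attr(X, "config") <- marker_config()
  class(X) <- c("app_feature_matrix", class(X))
  X
}

# Small cached synthetic cohorts so several test files can share one draw.
.synth_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n = 30, scale = 0.05, seed = 42,
                          effects = NULL) {
  key <- paste(n, scale, seed, paste(effects, collapse = ","), sep = "|")
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  cfg <- if (is.null(effects)) synth_config() else synth_config(effects = effects)
  co <- synth_generate(n, config = synth_scale(cfg, scale), seed = seed)
  co$intervals <- pair_intervals(co$events, co$window)
  co$fm <- extract_features(co$intervals, co$catalog, co$window,
                            labels = co$labels)
  .synth_cache[[key]] <- co
  co
}

label_vec <- function(ids, y01) {
  stats::setNames(ifelse(y01 == 1, "depressed", "nondepressed"), ids)
}
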