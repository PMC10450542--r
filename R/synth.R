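# Synthetic 7-day event-log cohorts with known group structure.
#
# Generation is top-down: per participant we first draw latent marker
# targets (education weekday duration, weekend photo-app spread, weekday
# app-choice concentration, communication-app diversity) from group-shifted
# distributions, then realize an event stream consistent with them. That
# makes parameter recovery -- extract the markers back out and test the
# group difference -- a well-posed check of the whole pipeline.

#' Effect configuration for the synthetic cohort
#'
#' Default effect sizes are standardized mean differences (Cohen's d) on
#' the latent marker targets; directions mirror the behavioral findings the
#' pipeline is meant to detect: nondepressed participants spend more
#' weekday time on education apps; depressed participants show a larger
#' weekend spread in photo/video app counts across diurnal periods, lower
#' weekday whole-smartphone usage entropy, and more diverse weekday
#' communication-app sets.
#'
#' @param prevalence Probability of the depressed label (default 0.51,
#'   51/100 in the motivating cohort).
#' @param events_per_phone Target mean number of fg/bg events per
#'   participant-week (default 8174, the reported cohort mean); scale down
#'   for tests with [synth_scale()].
#' @param effects Named effect sizes (`education_duration`,
#'   `photo_count_sd`, `smartphone_entropy`, `communication_diversity`),
#'   each `d >= 0`; 0 disables an effect.
#' @param gap_mix Probability that a drawn inter-session gap falls below
#'   the 45 s threshold (merging adjacent planned sessions), so
#'   segmentation is exercised on both sides of the threshold.
#' @return A `synth_config` list.
#' @export
synth_config <- function(prevalence = 0.51, events_per_phone = 8174,
                         effects = c(education_duration = 1,
                                     photo_count_sd = 1,
                                     smartphone_entropy = 1,
                                     communication_diversity = 1),
                         gap_mix = 0.15) {
  stopifnot(prevalence > 0, prevalence < 1, events_per_phone > 0,
            all(is.finite(effects)))
  need <- c("education_duration", "photo_count_sd", "smartphone_entropy",
            "communication_diversity")
  eff <- c(education_duration = 0, photo_count_sd = 0,
           smartphone_entropy = 0, communication_diversity = 0)
  eff[names(effects)] <- effects
  structure(list(prevalence = prevalence,
                 events_per_phone = events_per_phone,
                 effects = eff[need], gap_mix = gap_mix),
            class = "synth_config")
}

#' Scale the event volume of a synthetic configuration
#'
#' Marker targets (durations, spreads, diversity) are preserved; only the
#' event volume changes.
#'
#' @param config A [synth_config()].
#' @param factor Positive multiplier for `events_per_phone`.
#' @return The rescaled config.
#' @export
synth_scale <- function(config, factor) {
  stopifnot(inherits(config, "synth_config"), factor > 0)
  config$events_per_phone <- config$events_per_phone * factor
  config
}

synth_catalog <- function() {
  core <- c("Communication", "Social", "Tools", "Games", "Entertainment",
            "Music and Audio")
  rare <- c("Weather", "Finance", "Beauty", "Medical")
  napp <- function(cat) if (cat == "Communication") 10L else 6L
  cats <- c(core, "Education", "Photo and Video", rare)
  pkgs <- unlist(lapply(cats, function(cat) {
    slug <- tolower(gsub(" ", "", cat))
    paste0("com.synth.", slug, ".app", seq_len(napp(cat)))
  }))
  cat_of <- rep(cats, vapply(cats, napp, integer(1)))
  app_catalog(pkgs, cat_of)
}

# Spread a PHQ-9 total over 9 items, each capped at 3.
distribute_phq9 <- function(total) {
  items <- rep(0L, 9L)
  for (t in seq_len(total)) {
    open <- which(items < 3L)
    j <- open[sample.int(length(open), 1L)]
    items[j] <- items[j] + 1L
  }
  items
}

#' Generate a synthetic cohort of app-usage event logs
#'
#' Emits per-participant fg/bg event streams over 7 civil days with a
#' diurnal intensity profile, a session mixture straddling the
#' micro/review/engage bins and the 45 s gap threshold, PHQ-9 responses
#' consistent with each label (depressed iff total >= 10), an app catalog,
#' and a ground-truth table naming the planted markers.
#'
#' @param n Number of participants (>= 4).
#' @param window An [obs_window()]; default starts Monday 2020-08-03 with a
#'   Friday/Saturday weekend.
#' @param config A [synth_config()].
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return List with `events` (data.table:
#'   `participant_id,timestamp,package,kind`), `catalog`, `phq9`, `labels`
#'   (named vector), `truth` (planted-marker table), `window`, `config`.
#' @export
synth_generate <- function(n, window = obs_window("2020-08-03"),
                           config = synth_config(), seed = 1L) {
  stopifnot(n >= 4)
  set.seed(as.integer(seed))
  # volume calibration: events = 7 days x sessions/day x E[intervals] x 2
  mean_intervals_per_session <- 0.35 * 1 + 0.30 * 1.5 + 0.35 * 2.5
  s_day <- config$events_per_phone / (7 * 2 * mean_intervals_per_session)
  if (s_day < 2)
    stop("event volume too low to form sessions; increase events_per_phone")
  period_w <- c(Night = 0.25, Morning = 0.90, Afternoon = 1.00,
                Evening = 1.10)
  period_w <- period_w / sum(period_w)
  lam <- s_day * period_w  # sessions per period per day

  catalog <- synth_catalog()
  pkgs_all <- names(unclass(catalog))
  cat_all <- unname(unclass(catalog))
  pkg_of <- function(cat) pkgs_all[cat_all == cat]
  base_cats <- c("Communication", "Social", "Tools", "Games",
                 "Entertainment", "Music and Audio")
  rare_cats <- c("Weather", "Finance", "Beauty", "Medical")
  eff <- config$effects

  # labels: redraw until both classes have >= 2 members (deterministic
  # under the seed)
  repeat {
    lab01 <- stats::rbinom(n, 1L, config$prevalence)
    if (sum(lab01) >= 2 && sum(1 - lab01) >= 2) break
  }
  ids <- sprintf("P%03d", seq_len(n))
  labels <- stats::setNames(ifelse(lab01 == 1, "depressed", "nondepressed"),
                            ids)

  wstart <- as.numeric(window$start)
  day_starts <- wstart + 86400 * (0:6)
  day_is_weekend <- day_type(as.POSIXct(day_starts, origin = "1970-01-01",
                                        tz = "UTC"),
                             window$weekend_days) == "Weekend"
  period_off <- c(Night = 0, Morning = 21600, Afternoon = 43200,
                  Evening = 64800)

  phq_rows <- vector("list", n)
  ev_rows <- vector("list", n)

  for (i in seq_len(n)) {
    dep <- lab01[i]
    # --- latent marker targets -------------------------------------------
    edu_target <- max(0, stats::rnorm(1, 5400 - eff["education_duration"] *
                                        2700 * dep, 2700))
    photo_sd <- exp(stats::rnorm(1, log(0.7) + 0.8 *
                                   eff["photo_count_sd"] * dep, 0.30))
    alpha <- exp(stats::rnorm(1, log(1.5) - 1.1 *
                                eff["smartphone_entropy"] * dep, 0.25))
    comm_z <- stats::rnorm(1, eff["communication_diversity"] * dep, 1)

    # --- app inventory ----------------------------------------------------
    comm_pool <- pkg_of("Communication")
    n_comm <- max(2L, min(7L, round(2.5 + comm_z)))
    wts <- c(rep(4, 4), rep(exp(comm_z), 6))  # idiosyncratic tail opens with z
    inv_comm <- sample(comm_pool, n_comm, prob = wts)
    inv <- unlist(lapply(setdiff(base_cats, "Communication"), function(cat)
      sample(pkg_of(cat), 3L)))
    inv <- c(inv_comm, inv)
    for (cat in rare_cats)
      if (stats::runif(1) < 0.3)
        inv <- c(inv, sample(pkg_of(cat), sample(1:2, 1)))
    # weekday app-choice weights: Dirichlet with concentration alpha
    w_wd <- stats::rgamma(length(inv), shape = alpha); w_wd <- w_wd / sum(w_wd)
    w_we <- stats::rgamma(length(inv), shape = 1.2); w_we <- w_we / sum(w_we)

    iv_s <- numeric(0); iv_e <- numeric(0); iv_p <- character(0)
    add_iv <- function(s, e, p) {
      iv_s <<- c(iv_s, s); iv_e <<- c(iv_e, e); iv_p <<- c(iv_p, p)
    }

    # --- base sessions ----------------------------------------------------
    for (d in 1:7) {
      weekend <- day_is_weekend[d]
      w_app <- if (weekend) w_we else w_wd
      for (p in names(lam)) {
        npd <- stats::rpois(1, lam[[p]])
        if (npd == 0) next
        t <- day_starts[d] + period_off[[p]] + stats::runif(1, 0, 300)
        pend <- day_starts[d] + period_off[[p]] + 21600
        for (s in seq_len(npd)) {
          if (t >= pend) break
          ty <- sample(c("micro", "review", "engage"), 1,
                       prob = c(0.35, 0.30, 0.35))
          durs <- switch(ty,
            micro = stats::runif(1, 2, 15),
            review = {
              k <- sample(1:2, 1)
              tot <- stats::runif(1, 16, 60)
              rep(tot / k, k)
            },
            engage = {
              k <- sample(1:4, 1)
              dd <- stats::rlnorm(k, log(90), 0.8)
              if (sum(dd) <= 60) dd[k] <- dd[k] + (61 - sum(dd))
              dd
            })
          for (u in seq_along(durs)) {
            app <- sample(inv, 1, prob = w_app)
            add_iv(t, t + durs[u], app)
            t <- t + durs[u]
            if (u < length(durs)) t <- t + stats::runif(1, 1, 40)
          }
          gap <- if (stats::runif(1) < config$gap_mix)
            stats::runif(1, 10, 45) else 46 + stats::rexp(1, 1 / 120)
          t <- t + gap
        }
      }
    }

    # --- weekly touch of every owned communication app (weekdays) --------
    # ensures the used-app diversity marker reflects the drawn inventory
    # even under strong usage concentration
    wk_days0 <- which(!day_is_weekend)
    for (app in inv_comm) {
      d0 <- wk_days0[sample.int(length(wk_days0), 1)]
      p0 <- sample(c("Morning", "Afternoon", "Evening"), 1)
      t0 <- day_starts[d0] + period_off[[p0]] + stats::runif(1, 0, 21500)
      add_iv(t0, t0 + stats::runif(1, 20, 60), app)
    }

    # --- planted education weekday sessions ------------------------------
    if (edu_target > 0) {
      edu_apps <- pkg_of("Education")[1:3]
      wk_days <- which(!day_is_weekend)
      n_chunk <- max(1L, ceiling(edu_target / 600))
      chunk <- edu_target / n_chunk
      for (ch in seq_len(n_chunk)) {
        d <- wk_days[(ch - 1L) %% length(wk_days) + 1L]
        p <- sample(c("Morning", "Afternoon", "Evening"), 1)
        t0 <- day_starts[d] + period_off[[p]] + stats::runif(1, 0, 21600 - chunk)
        add_iv(t0, t0 + chunk, edu_apps[(ch - 1L) %% 3L + 1L])
      }
    }

    # --- planted weekend photo/video app spread --------------------------
    photo_apps <- pkg_of("Photo and Video")
    we_days <- which(day_is_weekend)
    k_per <- pmax(0L, round(stats::rnorm(4, 2, photo_sd)))
    names(k_per) <- names(period_off)
    for (p in names(k_per)) {
      if (k_per[[p]] == 0) next
      use <- photo_apps[seq_len(min(k_per[[p]], length(photo_apps)))]
      for (app in use) {
        d <- sample(we_days, 1)
        t0 <- day_starts[d] + period_off[[p]] + stats::runif(1, 0, 21300)
        add_iv(t0, t0 + stats::runif(1, 20, 55), app)
      }
    }

    # --- realize fg/bg events --------------------------------------------
    wend <- as.numeric(window$end)
    iv_e <- pmin(iv_e, wend)
    keep <- iv_e > iv_s
    ts <- c(iv_s[keep], iv_e[keep])
    kind <- rep(c("foreground", "background"), each = sum(keep))
    pkg <- rep(iv_p[keep], 2L)
    ord <- order(ts, kind == "foreground", pkg)
    ev_rows[[i]] <- data.table::data.table(
      participant_id = ids[i],
      timestamp = as.POSIXct(ts[ord], origin = "1970-01-01", tz = "UTC"),
      package = pkg[ord], kind = kind[ord])

    # --- PHQ-9 consistent with the label ---------------------------------
    tot <- if (dep == 1)
      sample(10:27, 1, prob = exp(-(10:27 - 10) / 6))
    else
      sample(0:9, 1, prob = exp(-abs(0:9 - 3) / 3))
    items <- distribute_phq9(tot)
    phq_rows[[i]] <- data.table::as.data.table(
      c(list(participant_id = ids[i]),
        stats::setNames(as.list(items), paste0("item", 1:9))))
  }

  truth <- data.table::data.table(
    marker = c("education_duration", "photo_count_sd", "smartphone_entropy",
               "communication_diversity"),
    feature = c("Weekday_Education_Duration_Total",
                "Weekend_Photo_and_Video_Number_of_Apps_6_Hour_SD",
                "Weekday_Smartphone_Entropy_Total",
                "Weekday_Communication_Number_of_Apps_Total"),
    family = c("Weekday_Education_Duration",
               "Weekend_Photo_and_Video_Number_of_Apps",
               "Weekday_Smartphone_Entropy",
               "Weekday_Communication_(Number_of_Apps|Ratio_of_Hamming)"),
    direction = c("nondepressed_higher", "depressed_higher",
                  "depressed_lower", "depressed_higher"),
    effect_d = as.numeric(config$effects))

  phq9 <- data.table::rbindlist(phq_rows)
  phq9[, total := phq9_score(as.matrix(.SD)), .SDcols = paste0("item", 1:9)]
  phq9[, label := phq9_classify(total)]
  stopifnot(identical(unname(labels), phq9$label))

  list(events = data.table::rbindlist(ev_rows), catalog = catalog,
       phq9 = phq9, labels = labels, truth = truth, window = window,
       config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `events.csv`, `catalog.csv`, `phq9.csv`, `truth.csv` in the
#' formats the readers ([read_events()], [read_catalog()], [read_phq9()])
#' expect.
#'
#' @param cohort Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- data.table::copy(cohort$events)
  ev[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%OS3")]
  data.table::fwrite(ev, file.path(dir, "events.csv"))
  cat_dt <- data.table::data.table(package = names(unclass(cohort$catalog)),
                                   category = unname(unclass(cohort$catalog)))
  data.table::fwrite(cat_dt, file.path(dir, "catalog.csv"))
  data.table::fwrite(cohort$phq9[, c("participant_id",
                                     paste0("item", 1:9)), with = FALSE],
                     file.path(dir, "phq9.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
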