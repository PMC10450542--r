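#' Diurnal period names, in canonical order
#' @return `c("Night","Morning","Afternoon","Evening")`
#' @export
diurnal_periods <- function() c("Night", "Morning", "Afternoon", "Evening")

# Period boundaries (seconds after local midnight), half-open:
# [00:00,06:00) Night, [06:00,12:00) Morning, [12:00,18:00) Afternoon,
# [18:00,24:00) Evening. The conventional ":01" phrasing of these period
# starts is read as inclusive-boundary notation so that the four periods
# tile the day exactly.
.period_len <- 21600

period_of_second <- function(sec_of_day) {
  diurnal_periods()[pmin(4L, sec_of_day %/% .period_len + 1L)]
}

#' Day-type (weekday/weekend) of a timestamp
#'
#' @param timestamp POSIXct (civil time).
#' @param weekend_days Integer ISO weekdays (1 = Monday .. 7 = Sunday) or
#'   names, as in [obs_window()].
#' @return Character vector, `"Weekday"` or `"Weekend"`.
#' @export
day_type <- function(timestamp, weekend_days = c("Fri", "Sat")) {
  wd <- normalize_weekdays(weekend_days)
  iso <- iso_weekday(timestamp)
  ifelse(iso %in% wd, "Weekend", "Weekday")
}

# ISO weekday 1=Mon..7=Sun from civil POSIXct without locale dependence.
iso_weekday <- function(timestamp) {
  days <- as.numeric(timestamp) %/% 86400  # 1970-01-01 was a Thursday (=4)
  as.integer((days + 3) %% 7 + 1)
}

#' Diurnal period containing a timestamp
#' @param timestamp POSIXct.
#' @return Character vector of period names.
#' @export
period_of <- function(timestamp) {
  period_of_second(as.numeric(timestamp) %% 86400)
}

#' Day-type and period a usage interval is launched in
#'
#' Launch counts are attributed wholly to the period containing the
#' interval's start, even when the interval crosses a period boundary.
#'
#' @param start POSIXct interval starts.
#' @inheritParams day_type
#' @return `data.table` with `day_type` and `period` columns.
#' @export
launch_period <- function(start, weekend_days = c("Fri", "Sat")) {
  data.table::data.table(day_type = day_type(start, weekend_days),
                         period = period_of(start))
}

#' Split interval durations at diurnal-period boundaries
#'
#' A usage interval crossing 06:00/12:00/18:00/24:00 contributes to every
#' period it overlaps: an app opened at 11:30 and closed at 12:20 adds 30
#' minutes to the morning and 20 minutes to the afternoon. Midnight
#' crossings also switch the day-type. Split durations always sum exactly to
#' the interval duration.
#'
#' @param intervals `data.table` from [pair_intervals()] (needs `start`,
#'   `end` as POSIXct and any id columns, which are carried through).
#' @inheritParams day_type
#' @return `data.table`: one row per (interval x period crossed) with the
#'   original columns plus `day_type`, `period`, `duration` (seconds).
#' @export
split_interval <- function(intervals, weekend_days = c("Fri", "Sat")) {
  dt <- data.table::as.data.table(intervals)
  s <- as.numeric(dt$start); e <- as.numeric(dt$end)
  if (any(e < s)) stop("interval end before start")
  # fast path: interval fully inside one 6-hour block
  blk_s <- s %/% .period_len; blk_e <- (e - 1e-9) %/% .period_len
  same <- blk_s == blk_e | e == s
  out <- vector("list", 2L)
  if (any(same)) {
    d1 <- dt[same]
    d1[, `:=`(day_type = day_type(start, weekend_days),
              period = period_of(start),
              duration = as.numeric(end) - as.numeric(start))]
    out[[1L]] <- d1
  }
  if (any(!same)) {
    d2 <- dt[!same]
    s2 <- s[!same]; e2 <- e[!same]
    pieces <- lapply(seq_len(nrow(d2)), function(i) {
      cuts <- seq((s2[i] %/% .period_len + 1) * .period_len, e2[i],
                  by = .period_len)
      edges <- unique(c(s2[i], cuts, e2[i]))
      data.table::data.table(row = i, seg_start = edges[-length(edges)],
                             seg_dur = diff(edges))
    })
    segs <- data.table::rbindlist(pieces)
    segs <- segs[seg_dur > 0]
    d2e <- d2[segs$row]
    ts <- as.POSIXct(segs$seg_start, origin = "1970-01-01", tz = "UTC")
    d2e[, `:=`(day_type = day_type(ts, weekend_days),
               period = period_of(ts), duration = segs$seg_dur)]
    out[[2L]] <- d2e
  }
  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  data.table::setorderv(res, intersect(c("participant_id", "start"),
                                       names(res)))
  res[]
}

#' Mean and population SD over the four diurnal periods
#'
#' Diurnal "mean"/"SD" marker characteristics summarize the four per-period
#' values of a measure. Unused periods must be zero-filled by the caller.
#' The SD uses the population divisor (4): the four periods are the entire
#' population of periods, not a sample.
#'
#' @param values Numeric vector of length 4 (Night, Morning, Afternoon,
#'   Evening order; order does not affect the result).
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
diurnal_stats <- function(values) {
  if (length(values) != 4L) stop("expected exactly 4 period values")
  if (anyNA(values)) return(c(mean = NA_real_, sd = NA_real_))
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}
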