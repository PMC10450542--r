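#' Define a 7-day observation window
#'
#' All timestamps in the pipeline are treated as local civil time (stored as
#' UTC POSIXct with no timezone arithmetic): diurnal periods are defined on
#' the local clock.
#'
#' @param start Window start, an ISO date or datetime string or POSIXct. The
#'   window covers exactly 7 civil days from `start`.
#' @param weekend_days Which weekdays count as weekend. Character
#'   abbreviations (`"Mon"`..`"Sun"`) or ISO numbers (1 = Monday ...
#'   7 = Sunday). Defaults to Friday/Saturday, the weekend in Bangladesh
#'   where the motivating cohort was collected; always configurable.
#' @return An `obs_window` list with `start`, `end` and integer
#'   `weekend_days`.
#' @export
obs_window <- function(start, weekend_days = c("Fri", "Sat")) {
  start <- as_civil_time(start)
  if (length(start) != 1L || is.na(start)) stop("invalid window start")
  wd <- normalize_weekdays(weekend_days)
  if (length(wd) < 1L || length(wd) >= 7L)
    stop("weekend_days must be a nonempty strict subset of the 7 weekdays")
  structure(list(start = start, end = start + 7 * 86400, weekend_days = wd),
            class = "obs_window")
}

normalize_weekdays <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1L | x > 7L)) stop("weekday numbers must be 1..7 (Mon..Sun)")
    return(sort(unique(x)))
  }
  abb <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  idx <- match(substr(as.character(x), 1, 3), abb)
  if (anyNA(idx)) stop("unknown weekday name(s): ", paste(x, collapse = ", "))
  sort(unique(idx))
}

# ISO-8601 (or date-only) strings -> POSIXct; unparseable entries give NA
# rather than an error so callers can collect row-level failures.
as_civil_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x),
                                                origin = "1970-01-01",
                                                tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read app-usage event logs
#'
#' Accepts CSV or JSON-lines with fields
#' `participant_id,timestamp,package,kind` where `kind` is `foreground` or
#' `background` and `timestamp` is ISO-8601. Malformed rows (bad timestamp,
#' bad kind, empty package) are collected and reported with their line
#' numbers rather than aborting, unless more than `max_bad_frac` of rows are
#' bad.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`.
#' @param max_bad_frac Abort when more than this fraction of rows fail to
#'   parse (default 0.1).
#' @return A `data.table` of events sorted by participant and timestamp
#'   (background before foreground at timestamp ties), with attribute
#'   `row_errors` (data.frame of line numbers + reasons).
#' @export
read_events <- function(path, format = c("csv", "jsonl"),
                        max_bad_frac = 0.1) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    line0 <- 1L  # header line
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    ok <- !vapply(recs, is.null, logical(1))
    df <- data.table::rbindlist(lapply(recs[ok], as.list), fill = TRUE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    line0 <- 0L
    if (!nrow(df)) {
      warning("empty event log: ", path)
      return(empty_events())
    }
  }
  need <- c("participant_id", "timestamp", "package", "kind")
  if (nrow(df) == 0L && format == "csv") {
    if (!all(need %in% names(df))) stop("event log is missing column(s): ",
                                        paste(setdiff(need, names(df)),
                                              collapse = ", "))
    warning("empty event log: ", path)
    return(empty_events())
  }
  if (!all(need %in% names(df)))
    stop("event log is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))

  ts <- as_civil_time(df$timestamp)
  kind <- tolower(trimws(df$kind))
  bad_ts <- is.na(ts)
  bad_kind <- !kind %in% c("foreground", "background")
  bad_pkg <- is.na(df$package) | !nzchar(df$package)
  bad <- bad_ts | bad_kind | bad_pkg
  errors <- data.frame(
    line = which(bad) + line0,
    reason = ifelse(bad_ts[bad], "unparseable timestamp",
                    ifelse(bad_kind[bad], "invalid kind", "empty package")),
    stringsAsFactors = FALSE)
  if (nrow(df) > 0 && mean(bad) > max_bad_frac)
    stop(sprintf("%d of %d rows failed to parse (> %.0f%%)",
                 sum(bad), nrow(df), 100 * max_bad_frac))

  ev <- data.table::data.table(
    participant_id = as.character(df$participant_id)[!bad],
    timestamp = ts[!bad],
    package = as.character(df$package)[!bad],
    kind = kind[!bad])
  ev <- sort_events(ev)
  data.table::setattr(ev, "row_errors", errors)
  ev[]
}

empty_events <- function() {
  data.table::data.table(participant_id = character(),
                         timestamp = as.POSIXct(character(), tz = "UTC"),
                         package = character(), kind = character())
}

# Canonical event order: participant, time, background before foreground at
# equal timestamps (prevents zero-length phantom overlaps), then package.
sort_events <- function(ev) {
  kind_rank <- ifelse(ev$kind == "background", 0L, 1L)
  ev[order(ev$participant_id, ev$timestamp, kind_rank, ev$package)]
}

#' Pair foreground/background events into usage intervals
#'
#' Per-package FIFO matching: each foreground opens an interval that the
#' next background of the same package closes. A second foreground for an
#' already-open package closes the first interval at the second foreground's
#' timestamp. Unmatched foregrounds are closed at the window end; unmatched
#' backgrounds are dropped. Intervals are clipped to the window; empty
#' results after clipping are removed.
#'
#' @param events Event `data.table` from [read_events()] (any row order;
#'   re-sorted internally with the documented tie-break).
#' @param window An [obs_window()].
#' @return `data.table` with `participant_id, package, start, end, duration`
#'   (duration in seconds).
#' @export
pair_intervals <- function(events, window) {
  stopifnot(inherits(window, "obs_window"))
  ev <- sort_events(data.table::as.data.table(events))
  if (!nrow(ev)) {
    return(data.table::data.table(participant_id = character(),
                                  package = character(),
                                  start = as.POSIXct(character(), tz = "UTC"),
                                  end = as.POSIXct(character(), tz = "UTC"),
                                  duration = numeric()))
  }
  wstart <- as.numeric(window$start); wend <- as.numeric(window$end)
  res <- ev[, pair_one_series(as.numeric(timestamp), kind, wend),
            by = .(participant_id, package)]
  res <- res[pmin(end, wend) > pmax(start, wstart)]
  res[, start := pmax(start, wstart)]
  res[, end := pmin(end, wend)]
  res[, duration := end - start]
  res[, start := as.POSIXct(start, origin = "1970-01-01", tz = "UTC")]
  res[, end := as.POSIXct(end, origin = "1970-01-01", tz = "UTC")]
  data.table::setorder(res, participant_id, start, package)
  res[]
}

# FIFO pairing within one (participant, package) series of numeric times.
pair_one_series <- function(times, kinds, wend) {
  starts <- numeric(0); ends <- numeric(0)
  open <- NA_real_
  for (i in seq_along(times)) {
    if (kinds[i] == "foreground") {
      if (!is.na(open)) {  # second foreground closes the first interval
        starts <- c(starts, open); ends <- c(ends, times[i])
      }
      open <- times[i]
    } else {
      if (!is.na(open)) {
        starts <- c(starts, open); ends <- c(ends, times[i])
        open <- NA_real_
      }  # unmatched background: dropped
    }
  }
  if (!is.na(open)) {  # unmatched foreground closed at window end
    starts <- c(starts, open); ends <- c(ends, wend)
  }
  list(start = starts, end = ends)
}
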