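#' Segment usage intervals into sessions by inter-use gap
#'
#' Consecutive intervals belong to the same session while the gap between
#' the end of device engagement so far and the next interval's start is at
#' most `gap_threshold` (default 45 s); a gap strictly greater than the
#' threshold starts a new session. Overlapping intervals (two apps used
#' concurrently) count a gap of zero for segmentation, but their durations
#' still sum into the session's active duration.
#'
#' @param intervals `data.table` from [pair_intervals()]; segmented within
#'   each participant, ordered by start.
#' @param gap_threshold Maximum in-session gap, seconds.
#' @return `data.table` of sessions: `participant_id, session_id, start,
#'   end, n_intervals, active_duration, type` where `type` comes from
#'   [type_session()].
#' @export
segment_sessions <- function(intervals, gap_threshold = 45) {
  dt <- data.table::as.data.table(intervals)
  if (!nrow(dt)) {
    return(data.table::data.table(
      participant_id = character(), session_id = integer(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"),
      n_intervals = integer(), active_duration = numeric(),
      type = character()))
  }
  data.table::setorder(dt, participant_id, start, end)
  dt[, `:=`(s = as.numeric(start), e = as.numeric(end))]
  dt[, session_id := {
    run_end <- cummax(data.table::shift(e, fill = s[1]))
    gap <- pmax(s - run_end, 0)  # negative gap (overlap) treated as 0
    cumsum(gap > gap_threshold) + 1L
  }, by = participant_id]
  out <- dt[, .(start = start[1L], end = as.POSIXct(max(e),
                                                    origin = "1970-01-01",
                                                    tz = "UTC"),
                n_intervals = .N, active_duration = sum(e - s)),
            by = .(participant_id, session_id)]
  out[, type := type_session(active_duration)]
  out[]
}

#' Type a session as micro / review / engage
#'
#' Micro: total active duration of at most 15 s. Review: more than 15 s and
#' up to 60 s. Engage: more than 60 s.
#'
#' @param active_duration Numeric seconds (vectorized).
#' @return Character vector in `{"micro","review","engage"}`.
#' @export
type_session <- function(active_duration) {
  if (any(active_duration < 0)) stop("negative session duration")
  ifelse(active_duration <= 15, "micro",
         ifelse(active_duration <= 60, "review", "engage"))
}

#' Count sessions by type within day-type and diurnal period
#'
#' A session is attributed (not split) to the day-type and period of its
#' start timestamp. `total` always equals `micro + review + engage`.
#'
#' @param sessions Output of [segment_sessions()].
#' @inheritParams day_type
#' @return `data.table` keyed by `participant_id, day_type, period` with
#'   integer columns `total, micro, review, engage`.
#' @export
session_counts <- function(sessions, weekend_days = c("Fri", "Sat")) {
  dt <- data.table::as.data.table(sessions)
  if (!nrow(dt)) {
    return(data.table::data.table(participant_id = character(),
                                  day_type = character(), period = character(),
                                  total = integer(), micro = integer(),
                                  review = integer(), engage = integer()))
  }
  dt[, `:=`(day_type = day_type(start, weekend_days),
            period = period_of(start))]
  out <- dt[, .(total = .N,
                micro = sum(type == "micro"),
                review = sum(type == "review"),
                engage = sum(type == "engage")),
            by = .(participant_id, day_type, period)]
  out[]
}
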