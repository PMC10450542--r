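#' Score PHQ-9 item responses
#'
#' The PHQ-9 has 9 items scored 0 ("not at all") to 3 ("nearly every day");
#' the total is their sum, 0-27. An 8-item mode drops item 9 (mirroring the
#' PHQ-8 robustness check) while keeping the same cutoff.
#'
#' @param items Integer vector of 9 item scores (or a matrix/data.frame with
#'   9 columns for several participants), each in 0..3.
#' @param n_items 9 (default) or 8 (drop item 9).
#' @return Integer total(s).
#' @export
phq9_score <- function(items, n_items = 9L) {
  if (!n_items %in% c(8L, 9L)) stop("n_items must be 8 or 9")
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1L)
       else as.matrix(items)
  if (ncol(m) != 9L) stop("expected exactly 9 items, got ", ncol(m))
  if (anyNA(m) || any(m < 0 | m > 3) || any(m != round(m)))
    stop("PHQ-9 items must be integers in 0..3")
  tot <- as.integer(rowSums(m[, seq_len(n_items), drop = FALSE]))
  if (is.null(dim(items))) tot[1L] else tot
}

#' Dichotomize a PHQ-9 total into depressed / nondepressed
#'
#' @param total Integer total score(s), 0..27.
#' @param cutoff Totals at or above this are labelled depressed (default 10,
#'   the conventional screening cutoff).
#' @return Character vector, `"depressed"` or `"nondepressed"`.
#' @export
phq9_classify <- function(total, cutoff = 10L) {
  if (any(total < 0 | total > 27)) stop("PHQ-9 totals must be in 0..27")
  ifelse(total >= cutoff, "depressed", "nondepressed")
}

#' Read PHQ-9 responses from CSV
#'
#' Expects columns `participant_id,item1..item9`.
#'
#' @param path CSV file path.
#' @param cutoff Passed to [phq9_classify()].
#' @param n_items Passed to [phq9_score()].
#' @return `data.table` with `participant_id`, `item1..item9`, `total`,
#'   `label`.
#' @export
read_phq9 <- function(path, cutoff = 10L, n_items = 9L) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", paste0("item", 1:9))
  if (!all(need %in% names(df)))
    stop("PHQ-9 file is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  items <- as.matrix(df[, paste0("item", 1:9)])
  dt <- data.table::as.data.table(df[, need])
  dt[, participant_id := as.character(participant_id)]
  dt[, total := phq9_score(items, n_items = n_items)]
  dt[, label := phq9_classify(total, cutoff = cutoff)]
  dt[]
}
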