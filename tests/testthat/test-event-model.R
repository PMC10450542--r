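test_that("read_events parses CSV, reports bad rows, sorts output", {
  w <- toy_window()
  # 100 rows, one with a broken timestamp
  ts <- format(toy_time(1, "08:00:00") + seq_len(100) * 60,
               "%Y-%m-%dT%H:%M:%OS3")
  ts[37] <- "not-a-time"
  df <- data.frame(participant_id = "p1", timestamp = ts,
                   package = "app.chat",
                   kind = rep(c("foreground", "background"), 50))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  ev <- read_events(f)
  expect_equal(nrow(ev), 99L)
  errs <- attr(ev, "row_errors")
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$line, 38L)  # +1 for the header
  expect_equal(errs$reason, "unparseable timestamp")
  expect_false(is.unsorted(ev$timestamp))

  # empty file: empty cohort with a warning
  f2 <- tempfile(fileext = ".csv")
  write.csv(df[0, ], f2, row.names = FALSE)
  expect_warning(ev2 <- read_events(f2), "empty")
  expect_equal(nrow(ev2), 0L)

  # missing column is a schema error; >10% bad rows is fatal
  f3 <- tempfile(fileext = ".csv")
  write.csv(df[, -3], f3, row.names = FALSE)
  expect_error(read_events(f3), "missing column")
  df$timestamp <- "nope"
  write.csv(df, f3, row.names = FALSE)
  expect_error(read_events(f3), "failed to parse")
})

test_that("read_events reads JSON-lines", {
  f <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"participant_id":"p1","timestamp":"2020-08-03T10:00:00","package":"a","kind":"foreground"}',
    '{"participant_id":"p1","timestamp":"2020-08-03T10:05:00","package":"a","kind":"background"}'),
    f)
  ev <- read_events(f, format = "jsonl")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$kind, c("foreground", "background"))
})

test_that("pair_intervals implements per-package FIFO with stated rules", {
  w <- toy_window()
  # trivial fg/bg pair
  ev <- make_events(list("p", toy_time(1, "10:00:00"), "A", "foreground"),
                    list("p", toy_time(1, "10:05:00"), "A", "background"))
  iv <- pair_intervals(ev, w)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$duration, 300)

  # interleaved packages pair independently
  ev <- make_events(list("p", toy_time(1, "10:00:00"), "A", "foreground"),
                    list("p", toy_time(1, "10:02:00"), "B", "foreground"),
                    list("p", toy_time(1, "10:03:00"), "B", "background"),
                    list("p", toy_time(1, "10:05:00"), "A", "background"))
  iv <- pair_intervals(ev, w)
  expect_equal(iv[package == "A", duration], 300)
  expect_equal(iv[package == "B", duration], 60)

  # unmatched foreground closes at the window end
  ev <- make_events(list("p", toy_time(7, "23:00:00"), "A", "foreground"))
  iv <- pair_intervals(ev, w)
  expect_equal(iv$end, w$end)
  expect_equal(iv$duration, 3600)

  # a second foreground closes the first interval; unmatched bg dropped
  ev <- make_events(list("p", toy_time(1, "10:00:00"), "A", "foreground"),
                    list("p", toy_time(1, "10:01:00"), "A", "foreground"),
                    list("p", toy_time(1, "10:04:00"), "A", "background"),
                    list("p", toy_time(1, "10:30:00"), "A", "background"))
  iv <- pair_intervals(ev, w)
  expect_equal(iv$duration, c(60, 180))
})

test_that("pairing is invariant to permutation given the tie-break rule", {
  w <- toy_window()
  base <- make_events(
    list("p", toy_time(1, "10:00:00"), "A", "foreground"),
    list("p", toy_time(1, "10:05:00"), "A", "background"),
    list("p", toy_time(1, "10:05:00"), "A", "foreground"),  # tie: bg first
    list("p", toy_time(1, "10:09:00"), "A", "background"))
  iv0 <- pair_intervals(base, w)
  set.seed(9)
  for (r in 1:10) {
    ivp <- pair_intervals(base[sample(.N)], w)
    expect_equal(ivp, iv0)
  }
  expect_equal(iv0$duration, c(300, 240))
})

test_that("intervals round-trip through CSV bit-exactly", {
  co <- cached_cohort(n = 6)
  iv <- co$intervals[1:50]
  f <- tempfile(fileext = ".csv")
  out <- data.table::copy(iv)
  out[, `:=`(start = sprintf("%.17g", as.numeric(start)),
             end = sprintf("%.17g", as.numeric(end)))]
  data.table::fwrite(out, f)
  back <- data.table::fread(f, colClasses = list(character = c("start", "end")))
  back[, `:=`(start = as.POSIXct(as.numeric(start), origin = "1970-01-01",
                                 tz = "UTC"),
              end = as.POSIXct(as.numeric(end), origin = "1970-01-01",
                               tz = "UTC"))]
  expect_identical(as.numeric(back$start), as.numeric(iv$start))
  expect_identical(as.numeric(back$end), as.numeric(iv$end))
  expect_identical(back$package, iv$package)
})

test_that("catalog categorizes with fallback and rejects conflicts", {
  cat <- toy_catalog()
  expect_equal(categorize("app.chat", cat), "Communication")
  expect_equal(categorize("who.dis", cat), "Tools")
  expect_equal(categorize(c("app.feed", "x", "app.cam"), cat),
               c("Social", "Tools", "Photo and Video"))
  # conflicting duplicate rows fail at load time; agreeing ones are fine
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(package = c("a", "a"),
                       category = c("Tools", "Games")), f, row.names = FALSE)
  expect_error(read_catalog(f), "conflicting")
  write.csv(data.frame(package = c("a", "a"),
                       category = c("Tools", "Tools")), f, row.names = FALSE)
  expect_silent(cat2 <- read_catalog(f))
  expect_equal(categorize("a", cat2), "Tools")
  expect_error(app_catalog("a", "NotACategory"), "unknown app categories")
})

test_that("per-package intervals never overlap and respect the window", {
  co <- cached_cohort(n = 6)
  iv <- co$intervals
  expect_true(all(iv$duration >= 0))
  expect_true(all(as.numeric(iv$start) >= as.numeric(co$window$start)))
  expect_true(all(as.numeric(iv$end) <= as.numeric(co$window$end)))
  overlaps <- iv[, {
    o <- order(start)
    s <- as.numeric(start)[o]; e <- as.numeric(end)[o]
    .(bad = any(s[-1] < e[-length(e)] - 1e-9))
  }, by = .(participant_id, package)]
  expect_false(any(overlaps$bad))
  # per-package weekly total cannot exceed the window length
  tot <- iv[, .(d = sum(duration)), by = .(participant_id, package)]
  expect_true(all(tot$d <= 7 * 86400 + 1e-6))
})
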