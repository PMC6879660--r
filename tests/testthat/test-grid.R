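test_that("resampling sums activity and averages position within an epoch", {
  raw_a <- tibble::tibble(time = week_start + 30 * (0:19), value = 3)
  out <- resample_to_grid(raw_a, "A", "sum")
  expect_equal(nrow(out), 1L)
  expect_equal(out$value, 60)

  raw_p <- tibble::tibble(time = week_start + c(0, 300), value = c(30, 60))
  expect_equal(resample_to_grid(raw_p, "P", "mean")$value, 45)
})

test_that("a 30-s stream covering 08:00:00-08:09:30 yields one 08:00 epoch", {
  t <- lubridate::ymd_hms("2019-11-25 08:00:00") + 30 * (0:19)
  out <- resample_to_grid(tibble::tibble(time = t, value = 1), "A", "sum")
  expect_equal(nrow(out), 1L)
  expect_equal(format(out$time, "%H:%M"), "08:00")
})

test_that("unsorted or duplicated timestamps are rejected with the offender", {
  t <- week_start + c(0, 60, 30, 90)
  expect_error(resample_to_grid(tibble::tibble(time = t, value = 1), "A"),
               "not time-sorted.*00:00:30")
  t2 <- week_start + c(0, 30, 30, 90)
  expect_error(resample_to_grid(tibble::tibble(time = t2, value = 1), "A"),
               "duplicate timestamp")
})

test_that("resampling with method=sum conserves mass over covered spans", {
  set.seed(11)
  t <- week_start + 30 * (0:(20 * 144 - 1))  # one full day at 30 s
  v <- rexp(length(t))
  out <- resample_to_grid(tibble::tibble(time = t, value = v), "A", "sum")
  expect_equal(sum(out$value), sum(v), tolerance = 1e-9)
  expect_equal(nrow(out), 144L)
})

test_that("mean waveform of identical days equals one day and is idempotent", {
  daily <- sin(2 * pi * (0:143) / 144) + 2
  wf <- mean_waveform(days_of(daily, 7))
  expect_equal(wf$value, daily)
  expect_true(all(wf$n == 7L))
  # a waveform of a single repeated day is unchanged by re-averaging
  wf2 <- mean_waveform(days_of(wf$value, 1), toy_mode = TRUE)
  expect_equal(wf2$value, wf$value)
})

test_that("two-day toy waveform averages slot-wise", {
  s <- toy_series(c(rep(0, 144), rep(1, 144)))
  wf <- mean_waveform(s, toy_mode = TRUE)
  expect_equal(wf$value, rep(0.5, 144))
})

test_that("waveform of noisy cosine stays within 3 SEM of the clean cosine", {
  set.seed(21)
  clean <- cos(2 * pi * ((0:143) + 0.5) / 144)
  noisy <- rep(clean, 7) + rnorm(7 * 144, 0, 0.5)
  wf <- mean_waveform(toy_series(noisy))
  sem <- 0.5 / sqrt(7)
  expect_true(all(abs(wf$value - clean) < 3 * sem))
})

test_that("waveform requires 7 complete days unless in toy mode", {
  s <- toy_series(rnorm(3 * 144))
  expect_error(mean_waveform(s), "7 complete days")
  expect_silent(mean_waveform(s, toy_mode = TRUE))
})

test_that("epoch-of-day mapping is a day x slot bijection over the week", {
  s <- toy_series(seq_len(7 * 144))
  slot <- epoch_slot(s$time)
  day <- as.integer(lubridate::as_date(s$time) - lubridate::as_date(s$time[1]))
  key <- day * 144L + slot
  expect_equal(sort(key), 0:(7 * 144 - 1))
})

test_that("group waveform averages subjects slot-wise", {
  wf0 <- mean_waveform(days_of(rep(0, 144), 7), toy_mode = TRUE)
  wf1 <- mean_waveform(days_of(rep(1, 144), 7), toy_mode = TRUE)
  both <- dplyr::bind_rows(
    dplyr::mutate(wf0, subject_id = "a"),
    dplyr::mutate(wf1, subject_id = "b")
  )
  g <- group_waveform(both)
  expect_equal(g$value, rep(0.5, 144))
  expect_equal(group_waveform(dplyr::mutate(wf1, subject_id = "a"))$value,
               wf1$value)
  expect_error(group_waveform(both[0, ]), "no waveforms")

  set.seed(5)
  m <- matrix(rnorm(10 * 144), nrow = 10)
  wfs <- purrr::map_dfr(1:10, function(i) {
    dplyr::mutate(mean_waveform(days_of(m[i, ], 7), toy_mode = TRUE),
                  subject_id = as.character(i))
  })
  expect_equal(group_waveform(wfs)$value, colMeans(m), tolerance = 1e-12)
})
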