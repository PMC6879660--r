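grid_week <- toy_series(rep(0, 7 * 144))$time

diary_of <- function(...) {
  iv <- list(...)
  tibble::tibble(
    subject_id = "S01",
    type = purrr::map_chr(iv, 1),
    start = lubridate::ymd_hms(purrr::map_chr(iv, 2)),
    end = lubridate::ymd_hms(purrr::map_chr(iv, 3))
  )
}

test_that("binary sleep follows the epoch-midpoint rule", {
  empty <- diary_of()[0, ]
  s0 <- binarize_sleep(empty, grid_week)
  expect_true(all(s0$value == 0))

  nightly <- diary_of(
    c("sleep", "2019-11-25 00:00:00", "2019-11-25 08:00:00"),
    c("sleep", "2019-11-26 00:00:00", "2019-11-26 08:00:00")
  )
  s <- binarize_sleep(nightly, grid_week)
  day1 <- s$value[1:144]
  expect_equal(sum(day1), 48)  # 8 h at 10-min epochs

  wrap <- diary_of(c("sleep", "2019-11-25 23:55:00", "2019-11-26 00:05:00"))
  sw <- binarize_sleep(wrap, grid_week)
  on <- format(sw$time[sw$value == 1], "%d %H:%M")
  expect_equal(on, "26 00:00")
})

test_that("binary sleep minutes match diary minutes up to quantization", {
  set.seed(47)
  for (k in 1:20) {
    n_iv <- sample(1:5, 1)
    st <- sort(runif(n_iv, 0, 7 * 1440 - 700))
    du <- runif(n_iv, 60, 600)
    st <- st[c(TRUE, diff(st) > 700)]  # keep non-overlapping
    iv <- tibble::tibble(subject_id = "S01", type = "sleep",
                         start = week_start + lubridate::dminutes(st),
                         end = week_start + lubridate::dminutes(st + du[seq_along(st)]))
    s <- binarize_sleep(iv, grid_week)
    total_diary <- sum(du[seq_along(st)])
    expect_lt(abs(sum(s$value) * 10 - total_diary), 10 * (length(st) + 1))
  }
})

test_that("sleep probability is the percentage of subjects asleep", {
  d1 <- diary_of(c("sleep", "2019-11-25 00:00:00", "2019-11-25 08:00:00"))
  d2 <- diary_of(c("sleep", "2019-11-25 12:00:00", "2019-11-25 20:00:00"))
  s_all <- dplyr::bind_rows(
    dplyr::mutate(binarize_sleep(d1, grid_week[1:144]), subject_id = "a"),
    dplyr::mutate(binarize_sleep(d2, grid_week[1:144]), subject_id = "b")
  )
  wf <- sleep_probability(s_all)
  expect_equal(wf$value[wf$slot == 10], 50)   # only subject a asleep
  expect_equal(wf$value[wf$slot == 80], 50)   # only subject b asleep
  expect_equal(wf$value[wf$slot == 130], 0)

  # direct-count oracle on a small synthetic cohort
  set.seed(49)
  mats <- purrr::map(1:10, ~ matrix(rbinom(144, 1, 0.3), nrow = 1))
  s10 <- purrr::imap_dfr(mats, function(m, i) {
    dplyr::mutate(toy_series(as.numeric(m), variable = "S"),
                  subject_id = as.character(i))
  })
  wf10 <- sleep_probability(s10)
  direct <- colMeans(do.call(rbind, mats)) * 100
  expect_equal(wf10$value, direct)
})

test_that("identical week collapses MSW, MSF and MSFsc with zero SJL", {
  days <- sprintf("2019-11-%02d", 25:30)
  iv <- purrr::map(days, ~ c("sleep", paste(.x, "00:00:00"),
                             paste(.x, "08:00:00")))
  st <- sleep_timing(do.call(diary_of, iv))
  expect_true(st$sufficient)
  expect_equal(st$MSW, parse_clock("04:00"))
  expect_equal(st$MSF, parse_clock("04:00"))
  expect_equal(st$MSFsc, parse_clock("04:00"))
  expect_equal(st$SJL, 0)
})

test_that("MSFsc worked example matches hand arithmetic to the minute", {
  # work nights Mon-Thu 00:00-07:00 (onset Sun-Thu class via Mon-Thu dates,
  # offset Mon-Fri class), one free night Sat 01:00-10:00
  iv <- purrr::map(25:28, function(d) {
    c("sleep", sprintf("2019-11-%02d 00:00:00", d),
      sprintf("2019-11-%02d 07:00:00", d))
  })
  iv <- c(iv, list(c("sleep", "2019-11-30 01:00:00", "2019-11-30 10:00:00")))
  st <- sleep_timing(do.call(diary_of, iv))
  expect_true(st$sufficient)
  expect_equal(st$SD_w, 7)
  expect_equal(st$SD_f, 9)
  expect_equal(st$MSF, parse_clock("05:30"))
  expect_equal(st$SD_week, 53 / 7)
  # MSFsc = 05:30 - (9 - 53/7)/2 h = 04:47.14
  expect_equal(st$MSFsc, 330 - (9 - 53 / 7) * 30)
  expect_equal(format_clock(st$MSFsc), "04:47")
  # correction never exceeds half the work/free duration gap
  expect_lte(abs(clock_diff(st$MSFsc, st$MSF)),
             (st$SD_f - st$SD_w) / 2 * 60)
})

test_that("no correction is applied when free sleep is not longer", {
  iv <- purrr::map(25:28, function(d) {
    c("sleep", sprintf("2019-11-%02d 00:00:00", d),
      sprintf("2019-11-%02d 09:00:00", d))
  })
  iv <- c(iv, list(c("sleep", "2019-11-30 01:00:00", "2019-11-30 08:00:00")))
  st <- sleep_timing(do.call(diary_of, iv))
  expect_equal(st$MSFsc, st$MSF)
})

test_that("insufficient nights flag the subject instead of failing", {
  iv <- diary_of(c("sleep", "2019-11-25 00:00:00", "2019-11-25 08:00:00"))
  st <- sleep_timing(iv)
  expect_false(st$sufficient)
  expect_true(is.na(st$MSFsc))
})

test_that("social jetlag is the absolute circular midsleep difference", {
  expect_equal(social_jetlag(parse_clock("03:00"), parse_clock("03:00")), 0)
  expect_equal(social_jetlag(parse_clock("03:00"), parse_clock("05:00")), 2)
  expect_equal(social_jetlag(parse_clock("23:30"), parse_clock("01:30")), 2)
})

test_that("diary sleep durations equal offset minus onset circularly", {
  rec <- simulate_subject(subject_params(seed = 17, diary_noise_sd = 0))
  sl <- rec$diary[rec$diary$type == "sleep", ]
  dur <- as.numeric(difftime(sl$end, sl$start, units = "hours"))
  expect_equal(dur, rep(rec$truth$sleep_duration, 7), tolerance = 1e-8)
})
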