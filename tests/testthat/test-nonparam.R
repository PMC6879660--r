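test_that("IS is 1 for identical non-constant days", {
  daily <- sin(2 * pi * (0:143) / 144) + 2
  expect_equal(interdaily_stability(days_of(daily, 7)), 1)
})

test_that("IS of the 2-day 4-slot toy equals the hand-computed 5/9", {
  s <- toy_series(c(1, 2, 3, 4, 3, 4, 5, 6), epoch_minutes = 360)
  expect_equal(interdaily_stability(s, epoch_minutes = 360, toy_mode = TRUE),
               5 / 9)
})

test_that("IS of i.i.d. noise is near p/N, well below 0.2", {
  set.seed(31)
  s <- toy_series(rnorm(7 * 144))
  expect_lt(interdaily_stability(s), 0.2)
})

test_that("IV of a slow sinusoid is near zero", {
  daily <- sin(2 * pi * (0:143) / 144)
  expect_lt(intradaily_variability(days_of(daily, 7)), 0.05)
})

test_that("IV of strict alternation is 4", {
  s <- toy_series(rep(c(0, 1), 7 * 72))
  iv <- intradaily_variability(s)
  expect_gt(iv, 2)
  expect_equal(iv, 4, tolerance = 1e-12)
})

test_that("IV of white noise is close to the theoretical 2", {
  set.seed(33)
  s <- toy_series(rnorm(1008))
  expect_equal(intradaily_variability(s), 2, tolerance = 0.1)
})

test_that("IS and IV reject zero-variance series", {
  s <- toy_series(rep(3, 7 * 144))
  expect_error(interdaily_stability(s), "zero total variance")
  expect_error(intradaily_variability(s), "zero variance")
})

test_that("M10 of a cosine peaking at 15:00 starts at 10:00", {
  wf <- mean_waveform(
    days_of(cos(2 * pi * (((0:143) + 0.5) / 6 - 15) / 24), 7), toy_mode = TRUE)
  ml <- ml_levels(wf, m_hours = 10, l_hours = 5)
  expect_equal(ml$M_onset, parse_clock("10:00"))
  expect_equal(ml$L_onset, parse_clock("00:30"))
  expect_equal(night_phase_marker(ml), parse_clock("03:00"))
})

test_that("constant waveform ties break to the earliest onset", {
  wf <- mean_waveform(days_of(rep(2.5, 144), 7), toy_mode = TRUE)
  ml <- ml_levels(wf, m_hours = 10, l_hours = 5)
  expect_equal(ml$M_level, 2.5)
  expect_equal(ml$L_level, 2.5)
  expect_equal(ml$M_onset, 0)
  expect_equal(ml$L_onset, 0)
})

test_that("window search equals the exhaustive oracle on random waveforms", {
  set.seed(37)
  for (k in 1:200) {
    v <- rnorm(144) + 3 * sin(2 * pi * (0:143) / 144 + runif(1, 0, 2 * pi))
    wf <- mean_waveform(days_of(v, 7), toy_mode = TRUE)
    hrs <- if (k %% 2 == 0) c(10, 5) else c(5, 10)
    got <- ml_levels(wf, m_hours = hrs[1], l_hours = hrs[2])
    want <- oracle_ml(v, hrs[1] * 6, hrs[2] * 6)
    expect_equal(got$M_level, want$M_level)
    expect_equal(got$M_onset, want$M_onset)
    expect_equal(got$L_level, want$L_level)
    expect_equal(got$L_onset, want$L_onset)
  }
})

test_that("window lengths follow the variable's acrophase", {
  expect_equal(ml_hours("WT"), c(m_hours = 5, l_hours = 10))
  expect_equal(ml_hours("S"), c(m_hours = 5, l_hours = 10))
  for (v in c("L", "ET", "A", "P", "TAP")) {
    expect_equal(ml_hours(v), c(m_hours = 10, l_hours = 5))
  }
})

test_that("relative amplitude follows (M - L) / (M + L)", {
  expect_equal(relative_amplitude(5, 0), 1)
  expect_equal(relative_amplitude(2, 2), 0)
  expect_equal(relative_amplitude(3, 1), 0.5)
  expect_error(relative_amplitude(0, 0), "positive")
  expect_error(relative_amplitude(1, 2), "M must be")
})

test_that("cohort NRA recodes the 5% tails and rescales the middle", {
  ra <- seq(0, 0.99, by = 0.01)
  nra <- normalize_ra_cohort(ra)
  expect_equal(nra[ra == max(ra)], 1)
  expect_equal(nra[ra == min(ra)], 0)
  q <- quantile(ra, c(0.05, 0.95), type = 7, names = FALSE)
  expect_equal(nra[ra == 0.50], (0.50 - q[1]) / (q[2] - q[1]))
  expect_warning(normalize_ra_cohort(seq(0, 1, length.out = 10)),
                 "fewer than 20")
  expect_error(suppressWarnings(normalize_ra_cohort(rep(0.5, 30))),
               "degenerate")
})

test_that("CFI endpoints and midpoint", {
  expect_equal(circadian_function_index(1, 0, 1), 1)
  expect_equal(circadian_function_index(0, 2, 0), 0)
  expect_equal(circadian_function_index(0.5, 1, 0.5), 0.5)
})

test_that("IS/IV/RA stay in their documented ranges on random data", {
  set.seed(39)
  for (k in 1:20) {
    v <- abs(rnorm(7 * 144, 5, 2)) + rep(3 * (sin(2 * pi * (0:143) / 144) + 1),
                                         7) * runif(1)
    s <- toy_series(v)
    expect_true(dplyr::between(interdaily_stability(s), 0, 1))
    expect_gte(intradaily_variability(s), 0)
    np <- nonparametric_indexes(s)
    expect_true(dplyr::between(np$RA, 0, 1))
    expect_gte(np$M_level, np$L_level)
  }
})
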