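npm_df <- function(times, ids = NULL) {
  tibble::tibble(
    subject_id = ids %||% sprintf("S%02d", seq_along(times)),
    npm = parse_clock(times)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("five subjects split 1/3/1 into E/N/L", {
  out <- classify_by_npm(npm_df(c("03:00", "03:30", "04:00", "04:30",
                                  "05:00")))
  expect_equal(as.character(out$class), c("E", "N", "N", "N", "L"))
})

test_that("50 distinct phases give exactly 10 E, 30 N, 10 L", {
  set.seed(59)
  times <- clock_wrap(240 + sample(seq(-150, 150, length.out = 50)))
  out <- classify_by_npm(npm_df(times))
  expect_equal(unname(table(out$class)[c("E", "N", "L")]),
               c(E = 10L, N = 30L, L = 10L), ignore_attr = TRUE)
})

test_that("classification is invariant to subject order and rotation", {
  set.seed(61)
  times <- clock_wrap(rnorm(25, 240, 80))
  base <- classify_by_npm(npm_df(times))
  perm <- sample(25)
  shuffled <- classify_by_npm(npm_df(times[perm],
                                     ids = sprintf("S%02d", perm)))
  restored <- shuffled$class[order(shuffled$subject_id)]
  expect_equal(as.character(restored),
               as.character(base$class[order(base$subject_id)]))

  rot <- classify_by_npm(npm_df(clock_wrap(times + 300)))
  expect_equal(as.character(rot$class), as.character(base$class))
})

test_that("phases straddling midnight rank before early-morning phases", {
  out <- classify_by_npm(npm_df(c("23:50", "03:00", "04:00", "04:30",
                                  "05:00", "05:10")))
  expect_equal(as.character(out$class[out$npm == parse_clock("23:50")]), "E")
})

test_that("a degenerate all-equal cohort is assigned all N with a warning", {
  expect_warning(out <- classify_by_npm(npm_df(rep("04:00", 8))),
                 "identical")
  expect_true(all(out$class == "N"))
})

test_that("MSFsc classification applies the same quantile rule", {
  msf <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                        MSFsc = parse_clock("02:00") + (0:9) * 30)
  out <- classify_by_msfsc(msf)
  expect_equal(as.character(out$class),
               c("E", "E", rep("N", 6), "L", "L"))
  same <- classify_by_npm(dplyr::rename(msf, npm = MSFsc))
  expect_equal(as.character(out$class), as.character(same$class))
})

test_that("agreement percentages are counted from the label pairs", {
  same <- chronotype_agreement(rep(c("E", "N", "L"), 4),
                               rep(c("E", "N", "L"), 4))
  expect_equal(same$summary$coincidence_pct, 100)
  expect_equal(same$summary$opposite_pct, 0)

  opp <- chronotype_agreement(rep("E", 5), rep("L", 5))
  expect_equal(opp$summary$opposite_pct, 100)

  acm <- c("E", "E", "N", "N", "N", "L", "L", "E", "N", "L")
  msf <- c("E", "N", "N", "N", "E", "L", "N", "L", "N", "E")
  ag <- chronotype_agreement(acm, msf)
  expect_equal(ag$summary$coincidence_pct, 50)
  expect_equal(ag$summary$one_step_pct, 30)
  expect_equal(ag$summary$opposite_pct, 20)
  expect_equal(sum(ag$summary[c("coincidence_pct", "one_step_pct",
                                "opposite_pct")]), 100)
  expect_equal(unname(ag$counts["E", "L"] + ag$counts["L", "E"]), 2)

  expect_error(chronotype_agreement(acm, msf[-1]), "same subjects")
})

test_that("empirical cutoffs fall inside the generator-implied night range", {
  cohort <- simulate_cohort(n = 25, seed = 67)
  npms <- purrr::map_dbl(cohort, ~ .x$truth$true_npm)
  out <- classify_by_npm(npm_df(format_clock(npms)))
  cuts <- c(attr(out, "cut_early"), attr(out, "cut_late"))
  # programmed mid-sleeps span roughly 02:00-06:30 at default settings
  expect_true(all(cuts > parse_clock("01:30") & cuts < parse_clock("07:00")))
  expect_lt(clock_diff(cuts[1], cuts[2]), 0)
})
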