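test_that("TMT dichotomization uses the interpolated 25th percentile with ties to high", {
  res <- dichotomize_tmt(c(1, 2, 3, 4))
  expect_equal(res$cutoff$value, 1.75)
  expect_equal(res$low, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$cutoff$method, "linear_interpolation_type7")

  # value exactly at the cutoff goes to the high group
  res2 <- dichotomize_tmt(c(2, 2, 2, 2))
  expect_false(any(res2$low))

  set.seed(1)
  v <- rlnorm(10000, log(6), 0.3)
  res3 <- dichotomize_tmt(v)
  frac <- mean(res3$low)
  expect_gte(frac, 0.24)
  expect_lte(frac, 0.26)
  # brute-force sort oracle: cutoff lies between the bracketing order stats
  sv <- sort(v)
  expect_gte(res3$cutoff$value, sv[floor(0.25 * (10000 - 1)) + 1])
  expect_lte(res3$cutoff$value, sv[ceiling(0.25 * (10000 - 1)) + 1])

  expect_error(dichotomize_tmt(c(5, NA, 6)), "missing")
  expect_error(dichotomize_tmt(c(5, -1, 6)), "nonpositive|missing")
})

test_that("dysphagia is FOIS 1-6; 7 is unrestricted intake", {
  expect_false(derive_dysphagia(7))
  expect_true(derive_dysphagia(1))
  expect_true(derive_dysphagia(6))
  expect_error(derive_dysphagia(0))
  expect_error(derive_dysphagia(8))
})

make_exams <- function(totals, t_days = seq_along(totals) - 1,
                       overrides = list()) {
  n <- length(totals)
  items <- matrix(0L, n, length(ORACLE_ITEMS),
                  dimnames = list(NULL, names(ORACLE_ITEMS)))
  # put everything on item 3 (visual fields, max 3) spilling to item 9
  for (i in seq_len(n)) {
    items[i, "i3"] <- min(totals[i], 3L)
    items[i, "i9"] <- min(max(totals[i] - 3L, 0L), 3L)
    items[i, "i11"] <- max(totals[i] - 6L, 0L)
  }
  for (nm in names(overrides)) items[, nm] <- overrides[[nm]]
  df <- data.frame(t_days = t_days, items)
  df$total <- as.integer(rowSums(items))
  df
}

test_that("END criteria fire on total, consciousness, motor and new-deficit paths", {
  # flat trajectory: nothing
  ex <- make_exams(c(4, 4, 4))
  r <- derive_end(ex)
  expect_false(r$end); expect_false(r$end4)

  # +2 total via a non-motor, non-consciousness item
  ex <- make_exams(c(4, 6))
  r <- derive_end(ex)
  expect_true(r$end); expect_false(r$end4)

  # motor subscore rises by 1 while the total rises by only 1
  ex <- make_exams(c(3, 3), overrides = list(i5a = c(1L, 2L)))
  expect_equal(ex$total, c(4, 5))
  r <- derive_end(ex)
  expect_true(r$end); expect_false(r$end4)

  # consciousness path
  ex <- make_exams(c(2, 2), overrides = list(i1a = c(0L, 1L)))
  r <- derive_end(ex)
  expect_true(r$end)

  # worsening after improvement, against the running minimum
  ex <- make_exams(c(10, 3, 7))
  r <- derive_end(ex)
  expect_true(r$end); expect_true(r$end4)
  expect_equal(r$max_total_increment, 4)
  # admission-only reference misses it
  r2 <- derive_end(ex, reference = "admission")
  expect_false(r2$end4)

  # new-deficit flag alone
  ex <- make_exams(c(5, 5))
  expect_true(derive_end(ex, new_deficit = TRUE)$end)

  # exams outside the window are ignored
  ex <- make_exams(c(4, 10), t_days = c(0, 25))
  expect_false(derive_end(ex)$end)
  expect_error(derive_end(make_exams(4, t_days = 25)), "window")
})

test_that("END agrees with the exhaustive pairwise-enumeration oracle", {
  set.seed(42)
  for (i in 1:1000) {
    ex <- random_trajectory()
    nd <- runif(1) < 0.1
    got <- tryCatch(derive_end(ex, new_deficit = nd),
                    error = function(e) NULL)
    if (is.null(got)) {
      expect_true(all(ex$t_days[-1] > 21) || nrow(ex) == 0)
      next
    }
    want <- end_oracle(ex, nd)
    expect_identical(got$end, want$end)
    expect_identical(got$end4, want$end4)
  }
})

test_that("END is monotone: a later, worse exam never clears the flag", {
  set.seed(7)
  for (i in 1:200) {
    ex <- random_trajectory(n_exams = sample(2:4, 1), max_t = 15)
    before <- derive_end(ex)$end
    worse <- ex[nrow(ex), , drop = FALSE]
    worse$t_days <- min(worse$t_days + 2, 21)
    worse$i3 <- min(worse$i3 + 2L, 3L)
    worse$i9 <- min(worse$i9 + 2L, 3L)
    worse$total <- sum(worse[1, names(ORACLE_ITEMS)])
    after <- derive_end(rbind(ex, worse))$end
    if (before) expect_true(after)
  }
})

test_that("END cause is passed through and sHT is validated against the 4-point rule", {
  expect_equal(classify_end_cause("progression", end = FALSE,
                                  max_total_increment = 0), "none")
  expect_silent(
    expect_equal(classify_end_cause("sHT", TRUE, 5), "sHT"))
  expect_warning(
    expect_equal(classify_end_cause("sHT", TRUE, 2), "sHT"),
    ">=4")
  expect_equal(classify_end_cause("none", TRUE, 3), "unknown")
})

test_that("recovery flags respect thresholds and eligibility exclusions", {
  r <- derive_recovery(10, 6, 2, 1, 1)
  expect_true(r$inhosp$recovered)          # delta exactly 4
  r <- derive_recovery(5, 3, 2, 1, 1)
  expect_true(r$inhosp$recovered)          # 40% exactly, rational compare
  r <- derive_recovery(5, 4, 2, 1, 1)
  expect_false(r$inhosp$recovered)         # 20%, under both thresholds
  r <- derive_recovery(0, 0, 2, 1, 1)
  expect_false(r$inhosp$eligible)          # admission NIHSS 0 excluded

  r <- derive_recovery(8, 5, 3, 3, 2)
  expect_false(r$postdischarge$recovered)  # strict inequality
  expect_true(r$chronic$recovered)
  r <- derive_recovery(8, 5, 0, 0, 0)
  expect_false(r$postdischarge$eligible)   # discharge mRS 0 excluded
  expect_false(r$chronic$eligible)         # 3-month mRS 0 excluded
  r <- derive_recovery(8, 5, 6, 6, 6)
  expect_false(r$postdischarge$eligible)   # dead at discharge
  r <- derive_recovery(8, 5, 4, 3, NA)
  expect_false(r$chronic$eligible)         # lost to follow-up
  expect_true(r$postdischarge$recovered)
})

test_that("infarct volume imputation uses the cohort median", {
  r <- impute_infarct_volume(c(0.1, NA, 0.3))
  expect_equal(r$values, c(0.1, 0.2, 0.3))
  expect_equal(r$n_imputed, 1L)
  r2 <- impute_infarct_volume(c(0.1, 0.3))
  expect_equal(r2$values, c(0.1, 0.3))
  expect_equal(r2$n_imputed, 0L)
  expect_error(impute_infarct_volume(c(NA_real_, NA_real_)), "all")
})

test_that("derived table partitions eligibility and matches per-subject rules", {
  tc <- test_cohort(n = 500, seed = 11)
  dat <- tc$dat
  n <- nrow(dat)
  excl <- attr(dat, "exclusions")

  # eligibility partition arithmetic
  expect_equal(sum(dat$inhosp_eligible) + excl$inhosp_excluded_nihss0, n)
  expect_equal(sum(dat$inhosp_eligible),
               sum(!is.na(dat$inhosp_recovery)))
  expect_equal(sum(!dat$inhosp_eligible), sum(dat$nihss_admission == 0))
  expect_equal(sum(!dat$postdischarge_eligible),
               sum(dat$mrs_discharge %in% c(0, 6)))
  expect_equal(sum(!dat$chronic_eligible),
               sum(dat$mrs_3mo %in% c(0, 6) | is.na(dat$mrs_1y)))

  # low-TMT fraction pinned near 25%
  expect_gte(mean(dat$low_tmt), 0.22)
  expect_lte(mean(dat$low_tmt), 0.27)
  expect_equal(dat$tmt_mean, (tc$sim$cohort$tmt_left +
                                tc$sim$cohort$tmt_right) / 2)

  # spot-check END flags against the per-subject reference implementation
  set.seed(3)
  for (id in sample(dat$subject_id, 25)) {
    ex <- tc$sim$nihss[tc$sim$nihss$subject_id == id, ]
    nd <- tc$sim$cohort$new_deficit_within_3w[tc$sim$cohort$subject_id == id]
    want <- derive_end(ex, new_deficit = nd)
    expect_identical(dat$end[dat$subject_id == id], want$end)
    expect_identical(dat$end4[dat$subject_id == id], want$end4)
  }
})
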