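test_that("2x2 odds ratios and Woolf intervals match hand calculation", {
  est <- odds_ratio_2x2(55, 96, 90, 359)
  expect_equal(est$or_point, 55 * 359 / (96 * 90), tolerance = 1e-12)
  expect_equal(round(est$or_point, 2), 2.29)
  expect_equal(round(est$ci_low, 2), 1.53)
  expect_equal(round(est$ci_high, 2), 3.42)
  expect_lt(est$p, 0.001)

  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or_point, 1)
  expect_equal(round(odds_ratio_2x2(43, 108, 63, 386)$or_point, 2), 2.44)

  # CI width shrinks as all cells scale up
  w1 <- with(odds_ratio_2x2(5, 7, 9, 11), log(ci_high) - log(ci_low))
  w4 <- with(odds_ratio_2x2(20, 28, 36, 44), log(ci_high) - log(ci_low))
  expect_lt(w4, w1)

  # zero cell triggers the flagged Haldane-Anscombe correction
  est0 <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(est0$continuity_corrected)
  expect_true(is.finite(est0$or_point))
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "margin")
})

test_that("group comparison picks chi-square, Fisher, t or rank test appropriately", {
  g <- rep(c(TRUE, FALSE), each = 100)
  same <- rep(c(TRUE, FALSE), 100)
  r <- compare_groups(same, g)
  expect_gt(r$p, 0.9)

  flags <- rep(c(TRUE, FALSE, TRUE, FALSE), c(55, 96, 90, 359))
  grp <- rep(c(TRUE, FALSE), c(151, 449))
  r2 <- compare_groups(flags, grp)
  expect_equal(r2$test, "chisq")
  expect_lt(r2$p, 0.001)

  # small counts (expected cell < 5): Fisher, agreeing with the
  # hypergeometric enumeration
  fl <- rep(c(TRUE, FALSE, TRUE, FALSE), c(1, 8, 7, 2))
  gr <- rep(c(TRUE, FALSE), c(9, 9))
  r3 <- compare_groups(fl, gr)
  expect_equal(r3$test, "fisher")
  expect_equal(r3$p, fisher_oracle(1, 8, 7, 2), tolerance = 1e-8)

  set.seed(5)
  r4 <- compare_groups(rnorm(200), rep(c(TRUE, FALSE), each = 100))
  expect_equal(r4$test, "t")
  r5 <- compare_groups(rlnorm(200, 0, 1.5), rep(c(TRUE, FALSE), each = 100))
  expect_equal(r5$test, "wilcoxon")
  expect_error(compare_groups(rnorm(10), rep(TRUE, 10)), "two groups")
})

test_that("adjusted effect with no covariates reproduces the crude OR and respects coding", {
  tc <- test_cohort(n = 500, seed = 21)
  dat <- tc$dat
  est <- adjusted_effect(dat, "low_tmt", "end", covariates = character(0),
                         method = "ML")
  tab <- table(dat$low_tmt, dat$end)
  crude <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(est$or_point, crude, tolerance = 1e-7)

  # flipping the exposure coding inverts the OR exactly
  dat$high_tmt <- !dat$low_tmt
  est_f <- adjusted_effect(dat, "high_tmt", "end",
                           covariates = character(0), method = "ML")
  expect_equal(est_f$or_point, 1 / est$or_point, tolerance = 1e-7)

  # continuous exposure per 1 mm decrease is the reciprocal direction
  est_c <- adjusted_effect(dat, "tmt_mean", "end",
                           covariates = character(0), method = "ML")
  est_d <- adjusted_effect(dat, "tmt_mean", "end",
                           covariates = character(0), method = "ML",
                           per_decrease = TRUE)
  expect_equal(est_d$or_point, 1 / est_c$or_point, tolerance = 1e-10)
  expect_match(est_d$scale_note, "decrease")

  expect_error(adjusted_effect(dat[dat$end, ], "low_tmt", "end"),
               "fewer than 2")
})

test_that("null-effect simulations cover OR = 1 at close to nominal rate", {
  null_es <- list(exposure_dysphagia = 0, exposure_end = 0,
                  exposure_inhosp = 0, exposure_postdis = 0,
                  exposure_chronic = 0, exposure_mrs3_direct = 0)
  reps <- 40
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    tc <- test_cohort(n = 600, seed = 2000 + r, effect_sizes = null_es)
    est <- adjusted_effect(tc$dat, "low_tmt", "end")
    covered[r] <- est$ci_low <= 1 && 1 <= est$ci_high
  }
  expect_gte(mean(covered), 0.85)
})

test_that("interaction scan: null p-values spread over [0,1], planted interactions found, rare strata penalized", {
  tc <- test_cohort(n = 2000, seed = 31)
  dat <- tc$dat
  set.seed(77)
  # 20 modifiers independent of everything: their p-for-interaction should
  # look uniform
  mods <- paste0("noise_", 1:20)
  for (m in mods) dat[[m]] <- rbinom(nrow(dat), 1, 0.5) == 1
  scan <- interaction_scan(dat, "low_tmt", "end", mods)
  expect_true(all(!scan$skipped))
  expect_gt(min(scan$p_interaction), 0)
  expect_gt(ks.test(scan$p_interaction, "punif")$p.value, 0.01)

  # planted effect modification: exposure works only when modifier present
  set.seed(78)
  dat$planted_mod <- rbinom(nrow(dat), 1, 0.5) == 1
  lp <- qlogis(0.15) + 1.4 * dat$low_tmt * dat$planted_mod
  dat$yint <- rbinom(nrow(dat), 1, plogis(lp)) == 1
  sc2 <- interaction_scan(dat, "low_tmt", "yint", "planted_mod",
                          covariates = c("age", "sex"))
  expect_lt(sc2$p_interaction, 0.05)
  expect_gt(sc2$or_mod1, sc2$or_mod0)

  # constant modifier is skipped with a reason
  dat$const_mod <- TRUE
  sc3 <- interaction_scan(dat, "low_tmt", "end", "const_mod")
  expect_true(sc3$skipped)

  # near-empty stratum: Firth path taken, finite estimates
  dat$rare_mod <- seq_len(nrow(dat)) <= 12
  sc4 <- interaction_scan(dat, "low_tmt", "end", "rare_mod",
                          covariates = c("age", "sex"))
  expect_equal(sc4$method, "Firth")
  expect_true(is.finite(sc4$or_mod1))
})
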