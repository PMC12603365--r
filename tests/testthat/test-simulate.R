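test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(0), "n_subjects")
  expect_error(sim_config(-5), "n_subjects")
  expect_error(sim_config(10, covariate_params = list(p_male = 1.4)),
               "proportion")
  expect_error(sim_config(10, covariate_params = list(age_sd = 0)), "SD")
  expect_error(sim_config(10, lesion_params = list(dim = c(4, 20, 20))),
               "dim")
  expect_error(sim_config(10, followup_loss_rate_1y = -0.1), "proportion")
})

test_that("a fixed seed reproduces the cohort and masks bit-identically", {
  cfg <- sim_config(150, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  l1 <- simulate_lesions(s1$cohort, cfg)
  l2 <- simulate_lesions(s2$cohort, cfg)
  expect_identical(l1$lesions$masks, l2$lesions$masks)

  # substreams: a different lesion configuration leaves covariates alone
  cfg2 <- sim_config(150, seed = 5,
                     lesion_params = list(size_meanlog = log(20)))
  s3 <- simulate_cohort(cfg2)
  expect_identical(s1$cohort$age, s3$cohort$age)
  expect_identical(s1$cohort$tmt_left, s3$cohort$tmt_left)
})

test_that("simulated marginals converge to the configured baseline distributions", {
  cfg <- sim_config(20000, seed = 12)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  cp <- cfg$covariate_params
  n <- nrow(co)

  within3se <- function(mean_obs, target, sd, n) {
    abs(mean_obs - target) <= 3 * sd / sqrt(n)
  }
  expect_true(within3se(mean(co$sex == "male"), cp$p_male,
                        sqrt(cp$p_male * (1 - cp$p_male)), n))
  # age is truncated at 65 so compare against the truncated-normal mean
  a <- (cp$age_min - cp$age_mean) / cp$age_sd
  b <- (cp$age_max - cp$age_mean) / cp$age_sd
  trunc_mean <- cp$age_mean + cp$age_sd * (dnorm(a) - dnorm(b)) /
    (pnorm(b) - pnorm(a))
  expect_true(within3se(mean(co$age), trunc_mean, sd(co$age), n))
  expect_true(within3se(mean(co$bmi), cp$bmi_mean, cp$bmi_sd, n))
  expect_true(within3se(mean(co$hypertension), cp$p_hypertension, 0.4, n))
  expect_true(within3se(mean(co$smoking),
                        cp$p_male * cp$p_smoking_male +
                          (1 - cp$p_male) * cp$p_smoking_female, 0.5, n))

  # TMT structure: lower in women, decreasing with age
  tmt <- (co$tmt_left + co$tmt_right) / 2
  expect_gt(mean(tmt[co$sex == "male"]), mean(tmt[co$sex == "female"]))
  expect_lt(cor(co$age, tmt), 0)
  expect_true(all(tmt > 0))
  expect_equal(co$bmi, co$weight_kg / (co$height_cm / 100)^2,
               tolerance = 1e-9)

  # follow-up loss near the configured rate
  expect_true(within3se(mean(is.na(co$mrs_1y)), cfg$followup_loss_rate_1y,
                        0.2, n))
})

test_that("NIHSS exams are legal, time-sorted, and totals equal item sums", {
  tc <- test_cohort(n = 300, seed = 9)
  ns <- tc$sim$nihss
  items <- as.matrix(ns[names(ORACLE_ITEMS)])
  expect_true(all(items >= 0))
  expect_true(all(sweep(items, 2, ORACLE_ITEMS, "<=")))
  expect_equal(ns$total, as.integer(rowSums(items)))
  expect_true(all(tapply(ns$t_days, ns$subject_id,
                         function(t) !is.unsorted(t))))
})

test_that("zeroed exposure effects give crude odds ratios near 1", {
  null_es <- list(exposure_dysphagia = 0, exposure_end = 0,
                  exposure_inhosp = 0, exposure_postdis = 0,
                  exposure_chronic = 0, exposure_mrs3_direct = 0)
  tc <- test_cohort(n = 6000, seed = 55, effect_sizes = null_es)
  dat <- tc$dat
  for (o in c("dysphagia", "end", "mrs3_ge3")) {
    tab <- table(dat$low_tmt, dat[[o]])
    or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
    # exposure correlates with age/NIHSS, so the crude OR is near, not at, 1
    expect_gt(or, 0.75)
    expect_lt(or, 1.45)
  }
})

test_that("lesion blobs are contiguous, on-grid, and volumes recompute correctly", {
  cfg <- sim_config(80, seed = 13)
  sim <- simulate_cohort(cfg)
  les <- simulate_lesions(sim$cohort, cfg)
  dims <- les$lesions$dim
  nvox <- prod(dims)

  # contiguity by flood fill from the first voxel (independent check)
  neigh <- function(idx) {
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    i0 <- idx - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
    c(if (x > 0) idx - 1L, if (x < nx - 1) idx + 1L,
      if (y > 0) idx - nx, if (y < ny - 1) idx + nx,
      if (z > 0) idx - nx * ny, if (z < nz - 1) idx + nx * ny)
  }
  for (m in les$lesions$masks[1:20]) {
    expect_true(all(m >= 1 & m <= nvox))
    seen <- m[1]
    frontier <- m[1]
    mset <- m
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, neigh)))
      nb <- setdiff(intersect(nb, mset), seen)
      seen <- c(seen, nb)
      frontier <- nb
    }
    expect_setequal(seen, m)
  }
  expect_equal(les$cohort$infarct_volume_pct,
               unname(100 * lengths(les$lesions$masks) / nvox))

  # worked volume examples
  brain <- rep(TRUE, 8000)
  expect_equal(infarct_volume_pct(1:8, brain), 0.1)
  expect_equal(infarct_volume_pct(integer(0), brain), 0)
})
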