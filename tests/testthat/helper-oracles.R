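# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation (exhaustive enumeration,
# generic optimisation) so agreement is informative.

# NIHSS item maxima, duplicated here on purpose so the oracle does not
# depend on package internals
ORACLE_ITEMS <- c(i1a = 3L, i1b = 2L, i1c = 2L, i2 = 2L, i3 = 3L, i4 = 3L,
                  i5a = 4L, i5b = 4L, i6a = 4L, i6b = 4L, i7 = 2L, i8 = 2L,
                  i9 = 3L, i10 = 2L, i11 = 2L)

# END by exhaustive enumeration over all exam pairs (i < j) within the
# window: equivalent to the running-minimum rule
end_oracle <- function(exams, new_deficit = FALSE, window_days = 21) {
  ex <- exams[exams$t_days <= window_days, , drop = FALSE]
  total <- ex$total
  consc <- rowSums(ex[c("i1a", "i1b", "i1c")])
  motor <- rowSums(ex[c("i5a", "i5b", "i6a", "i6b")])
  m <- nrow(ex)
  end <- isTRUE(new_deficit)
  end4 <- FALSE
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (total[j] - total[i] >= 2) end <- TRUE
        if (total[j] - total[i] >= 4) end4 <- TRUE
        if (consc[j] - consc[i] >= 1) end <- TRUE
        if (motor[j] - motor[i] >= 1) end <- TRUE
      }
    }
  }
  list(end = end, end4 = end4)
}

# random serial-exam table with arbitrary (non-monotone) item trajectories
random_trajectory <- function(n_exams = NULL, max_t = 28) {
  if (is.null(n_exams)) n_exams <- sample(1:6, 1)
  t_days <- sort(sample(0:max_t, n_exams))
  t_days[1] <- 0
  items <- sapply(ORACLE_ITEMS, function(mx) sample(0:mx, n_exams,
                                                    replace = TRUE,
                                                    prob = (mx:0 + 1)^2))
  items <- matrix(as.integer(items), n_exams,
                  dimnames = list(NULL, names(ORACLE_ITEMS)))
  df <- data.frame(t_days = t_days, items)
  df$total <- as.integer(rowSums(items))
  df
}

# two-sided Fisher p by hypergeometric point-probability enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Firth estimates by direct numerical maximisation of the Jeffreys-penalized
# log-likelihood (generic optimiser, nothing shared with the IRLS path)
firth_optim_oracle <- function(x, y) {
  pen_ll <- function(beta) {
    eta <- drop(x %*% beta)
    w <- plogis(eta) * (1 - plogis(eta))
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(crossprod(x, x * w))$modulus[1]
  }
  opt <- optim(numeric(ncol(x)), function(b) -pen_ll(b), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

# small default-structure cohort for tests that just need realistic data
test_cohort <- function(n = 400, seed = 99, ...) {
  cfg <- sim_config(n, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  list(cfg = cfg, sim = sim,
       dat = analysis_table(sim$cohort, sim$nihss))
}
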