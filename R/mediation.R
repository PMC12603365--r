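#' Screen candidate mediators for independent association
#'
#' A candidate enters the mediation model only if it shows an independent
#' (covariate-adjusted) association with both the exposure and the
#' outcome at p < 0.05 (Wald): exposure -> candidate from a logistic model
#' of the candidate on exposure plus covariates, and candidate -> outcome
#' from a logistic model of the outcome on the candidate, the exposure and
#' covariates.
#'
#' @param data analysis data frame.
#' @param candidates character vector of binary candidate mediator
#'   columns.
#' @param exposure,outcome column names.
#' @param covariates covariate columns.
#' @param alpha significance level for entry.
#' @return data frame: \code{candidate}, \code{p_exposure},
#'   \code{p_outcome}, \code{admitted}.
#' @export
mediator_entry_screen <- function(data, candidates, exposure, outcome,
                                  covariates = covariate_set(),
                                  alpha = 0.05) {
  rows <- lapply(candidates, function(m) {
    p_exp <- tryCatch(
      adjusted_effect(data, exposure, m, covariates)$p,
      error = function(e) NA_real_)
    p_out <- tryCatch({
      keep <- stats::complete.cases(data[c(m, exposure, outcome, covariates)])
      df <- data[keep, , drop = FALSE]
      des <- logistic_design(df, c(m, exposure, covariates))
      y <- as.numeric(df[[outcome]])
      fit <- fit_auto(des$x, y)
      term <- grep(paste0("^", m), fit$terms, value = TRUE)[1]
      i <- match(term, fit$terms)
      2 * pnorm(-abs(fit$beta[i] / fit$se[i]))
    }, error = function(e) NA_real_)
    data.frame(candidate = m, p_exposure = p_exp, p_outcome = p_out,
               admitted = isTRUE(p_exp < alpha) && isTRUE(p_out < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# mediator-model probabilities under exposure setting a, and the outcome
# probability for given mediator values under exposure setting a
.mediation_machinery <- function(df, exposure, outcome, mediators,
                                 covariates) {
  desm <- logistic_design(df, c(exposure, covariates))
  Xm <- desm$x
  exp_col <- grep(paste0("^", exposure), colnames(Xm))[1]
  med_fits <- lapply(mediators, function(m) {
    fit_auto(Xm, as.numeric(df[[m]]))
  })
  names(med_fits) <- mediators
  deso <- logistic_design(df, c(exposure, mediators, covariates))
  Xo <- deso$x
  yo <- as.numeric(df[[outcome]])
  out_fit <- fit_auto(Xo, yo)
  med_cols <- vapply(mediators, function(m) {
    grep(paste0("^", m), colnames(Xo))[1]
  }, integer(1))
  exp_col_o <- grep(paste0("^", exposure), colnames(Xo))[1]

  med_prob <- function(a) {
    X <- Xm
    X[, exp_col] <- a
    sapply(mediators, function(m) plogis(drop(X %*% med_fits[[m]]$beta)))
  }
  # P(Y=1 | exposure=a, mediator draw M (n x k matrix), covariates)
  out_prob <- function(a, M) {
    X <- Xo
    X[, exp_col_o] <- a
    X[, med_cols] <- M
    plogis(drop(X %*% out_fit$beta))
  }
  list(med_prob = med_prob, out_prob = out_prob,
       med_fits = med_fits, out_fit = out_fit)
}

# Monte-Carlo counterfactual means; returns point estimates and the
# per-draw values used for MC standard errors
.mediation_estimates <- function(mach, mediators, mc_draws) {
  k <- length(mediators)
  p1 <- mach$med_prob(1)   # n x k
  p0 <- mach$med_prob(0)
  n <- nrow(p1)
  draws <- matrix(NA_real_, mc_draws, 3 + k,
                  dimnames = list(NULL, c("y11", "y10", "y00",
                                          paste0("y1_", mediators))))
  for (d in seq_len(mc_draws)) {
    u <- matrix(runif(n * k), n, k)
    M1 <- (u < p1) * 1
    M0 <- (u < p0) * 1   # common random numbers across settings
    draws[d, "y11"] <- mean(mach$out_prob(1, M1))
    draws[d, "y10"] <- mean(mach$out_prob(1, M0))
    draws[d, "y00"] <- mean(mach$out_prob(0, M0))
    for (j in seq_len(k)) {
      Mj <- M0
      Mj[, j] <- M1[, j]
      draws[d, 3 + j] <- mean(mach$out_prob(1, Mj))
    }
  }
  est <- colMeans(draws)
  total <- est["y11"] - est["y00"]
  direct <- est["y10"] - est["y00"]
  indirect <- est["y11"] - est["y10"]
  per_med <- est[3 + seq_len(k)] - est["y10"]
  names(per_med) <- mediators
  list(total = unname(total), direct = unname(direct),
       indirect_combined = unname(indirect), indirect = per_med,
       mc_se = apply(draws, 2, sd) / sqrt(mc_draws))
}

#' Multi-mediator counterfactual mediation analysis
#'
#' Decomposes the exposure effect on a binary outcome into a natural
#' direct effect and natural indirect effects through parallel binary
#' mediators, on the risk-difference scale. One logistic model is fitted
#' per mediator (mediator ~ exposure + covariates) and one for the
#' outcome (outcome ~ exposure + mediators + covariates); counterfactual
#' means are computed by Monte-Carlo integration over mediator draws
#' under exposed/unexposed settings (common random numbers across
#' settings), and all uncertainty comes from a percentile bootstrap over
#' subjects with full model refits. Deterministic given \code{seed}.
#'
#' The total effect equals direct + combined indirect by construction;
#' per-mediator indirect effects (shifting one mediator's distribution at
#' a time) sum to the combined indirect only approximately, since the
#' outcome model is nonlinear. The proportion mediated
#' (combined indirect / total) is reported only when the two share sign.
#'
#' @param data analysis data frame.
#' @param exposure,outcome binary column names.
#' @param mediators character vector of binary mediator columns
#'   (nonempty).
#' @param covariates covariate columns.
#' @param n_boot bootstrap replicates (>= 200 for reported CIs).
#' @param mc_draws Monte-Carlo draws per counterfactual integral.
#' @param seed integer seed for draws and bootstrap.
#' @param conf_level confidence level for percentile intervals.
#' @return a \code{mediation_result}: list with \code{total},
#'   \code{direct}, \code{indirect_combined}, \code{indirect}
#'   (per-mediator), \code{proportion_mediated}, matching \code{ci_*}
#'   percentile intervals, \code{mc_se}, \code{models}, \code{n},
#'   \code{n_dropped}, \code{n_boot}.
#' @export
mediate <- function(data, exposure, outcome, mediators,
                    covariates = covariate_set(), n_boot = 200,
                    mc_draws = 100, seed = 1L, conf_level = 0.95) {
  if (!length(mediators)) stop("mediators must be nonempty")
  if (n_boot < 200) {
    warning("n_boot < 200; reported CIs are unstable", call. = FALSE)
  }
  keep <- stats::complete.cases(
    data[c(exposure, outcome, mediators, covariates)])
  df <- data[keep, , drop = FALSE]
  n <- nrow(df)
  set.seed(substream_seed(seed, 7L))

  point_of <- function(d) {
    mach <- .mediation_machinery(d, exposure, outcome, mediators, covariates)
    .mediation_estimates(mach, mediators, mc_draws)
  }
  point <- point_of(df)

  k <- length(mediators)
  boot <- matrix(NA_real_, n_boot, 3 + k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(point_of(df[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(est)) next
    boot[b, ] <- c(est$total, est$direct, est$indirect_combined,
                   est$indirect)
  }
  alpha <- (1 - conf_level) / 2
  qs <- function(j) {
    v <- boot[, j]
    v <- v[is.finite(v)]
    if (length(v) < 10) c(NA_real_, NA_real_)
    else unname(stats::quantile(v, c(alpha, 1 - alpha)))
  }
  prop <- if (sign(point$indirect_combined) == sign(point$total) &&
              point$total != 0) {
    point$indirect_combined / point$total
  } else NA_real_
  prop_boot <- boot[, 3] / boot[, 1]
  prop_ci <- if (!is.na(prop)) {
    v <- prop_boot[is.finite(prop_boot)]
    unname(stats::quantile(v, c(alpha, 1 - alpha)))
  } else c(NA_real_, NA_real_)

  structure(list(
    total = point$total, direct = point$direct,
    indirect_combined = point$indirect_combined,
    indirect = point$indirect,
    proportion_mediated = prop,
    ci_total = qs(1), ci_direct = qs(2), ci_indirect_combined = qs(3),
    ci_indirect = lapply(seq_len(k), function(j) qs(3 + j)),
    ci_proportion = prop_ci,
    mc_se = point$mc_se,
    mediators = mediators,
    n = n, n_dropped = sum(!keep), n_boot = n_boot,
    scale = "risk difference"
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%+.4f (%+.4f, %+.4f)", v, ci[1], ci[2])
  cat("Counterfactual mediation (risk-difference scale), n =", x$n, "\n")
  cat("  total effect:    ", fmt(x$total, x$ci_total), "\n")
  cat("  direct effect:   ", fmt(x$direct, x$ci_direct), "\n")
  cat("  indirect (all):  ",
      fmt(x$indirect_combined, x$ci_indirect_combined), "\n")
  for (j in seq_along(x$mediators)) {
    cat(sprintf("    via %-18s %s\n", paste0(x$mediators[j], ":"),
                fmt(x$indirect[j], x$ci_indirect[[j]])))
  }
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated: %.1f%% (%.1f%%, %.1f%%)\n",
                100 * x$proportion_mediated, 100 * x$ci_proportion[1],
                100 * x$ci_proportion[2]))
  }
  invisible(x)
}
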