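#' The predefined covariate adjustment set
#'
#' Column names of the predefined covariates entered into every
#' multivariable model: age, sex, admission NIHSS, BMI, pre-stroke mRS,
#' previous stroke, hypertension, diabetes, hyperlipidaemia, atrial
#' fibrillation, coronary artery disease, smoking, stroke subtype
#' (reference-coded, large-artery atherosclerosis reference),
#' revascularization therapy, haemoglobin, total cholesterol, and infarct
#' volume (median-imputed \% of brain).
#'
#' @param include_infarct_volume drop the total infarct volume covariate
#'   (done in ROI-wise brain mapping, where it is collinear with the
#'   per-ROI lesion burden).
#' @return character vector of column names, in fixed order.
#' @export
covariate_set <- function(include_infarct_volume = TRUE) {
  covs <- c("age", "sex", "nihss_admission", "bmi", "pre_mrs",
            "prev_stroke", "hypertension", "diabetes", "hyperlipidaemia",
            "atrial_fibrillation", "coronary_artery_disease", "smoking",
            "stroke_subtype", "revascularization", "haemoglobin",
            "total_cholesterol")
  if (include_infarct_volume) covs <- c(covs, "infarct_volume_pct_imputed")
  covs
}

#' Odds ratio for a 2x2 table with a Woolf confidence interval
#'
#' Point estimate \eqn{ad/bc}; 95\% CI by the Woolf (log) method,
#' \eqn{\exp(\log OR \pm z \sqrt{1/a+1/b+1/c+1/d})}; two-sided p from the
#' Wald z statistic on the log scale. A zero cell triggers the
#' Haldane-Anscombe correction (0.5 added to all four cells), flagged in
#' the result.
#'
#' @param a,b,c,d nonnegative integer counts: exposed-event,
#'   exposed-nonevent, unexposed-event, unexposed-nonevent.
#' @param conf_level confidence level.
#' @return an \code{effect_estimate}: list with \code{or_point},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{continuity_corrected},
#'   \code{scale_note}.
#' @examples
#' odds_ratio_2x2(55, 96, 90, 359)  # dysphagia, low vs high TMT
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("zero margin; odds ratio undefined")
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  log_or <- log(counts["a"]) + log(counts["d"]) -
    log(counts["b"]) - log(counts["c"])
  se <- sqrt(sum(1 / counts))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- log_or / se
  structure(list(
    or_point = unname(exp(log_or)),
    ci_low = unname(exp(log_or - zq * se)),
    ci_high = unname(exp(log_or + zq * se)),
    p = unname(2 * pnorm(-abs(z))),
    continuity_corrected = corrected,
    scale_note = "odds ratio, exposed vs unexposed"
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g", x$or_point,
              x$ci_low, x$ci_high, x$p))
  if (isTRUE(x$continuity_corrected)) cat("  [Haldane-Anscombe corrected]")
  if (!is.null(x$scale_note)) cat("\n  scale:", x$scale_note)
  cat("\n")
  invisible(x)
}

#' Two-group comparison with automatic test choice
#'
#' Binary variables: Pearson chi-square without continuity correction,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5. Continuous variables: Student's t-test when a Shapiro-Wilk
#' test accepts normality in both groups (p > 0.05; on a subsample of
#' 5000 when larger), otherwise the Mann-Whitney U-test.
#'
#' @param values numeric or logical vector.
#' @param group logical or two-level factor defining the two groups.
#' @return list with \code{test} (name of the test used),
#'   \code{statistic}, and \code{p}.
#' @export
compare_groups <- function(values, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) stop("exactly two groups required")
  g <- droplevels(g)
  if (is.logical(values) || all(values %in% c(0, 1), na.rm = TRUE)) {
    tab <- table(factor(as.numeric(values), levels = c(1, 0)), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      list(test = "fisher", statistic = unname(ft$estimate), p = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      list(test = "chisq", statistic = unname(ct$statistic), p = ct$p.value)
    }
  } else {
    normal <- vapply(levels(g), function(l) {
      v <- values[g == l & !is.na(values)]
      if (length(v) < 3 || length(unique(v)) < 3) return(FALSE)
      if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
      stats::shapiro.test(v)$p.value > 0.05
    }, logical(1))
    if (all(normal)) {
      tt <- stats::t.test(values ~ g)
      list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- stats::wilcox.test(values ~ g, exact = FALSE)
      list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
    }
  }
}

# events-per-stratum rule deciding when a model drops to Firth penalization
needs_firth <- function(y, strata = NULL, min_count = 8L) {
  if (is.null(strata)) strata <- rep(1L, length(y))
  for (s in unique(strata)) {
    ys <- y[strata == s]
    if (sum(ys) < min_count || sum(1 - ys) < min_count) return(TRUE)
  }
  FALSE
}

# ML with automatic Firth fallback on rare events, separation, or
# non-convergence; separation warnings are absorbed because the fallback
# handles them
fit_auto <- function(x, y, strata = NULL, force = NULL) {
  use <- if (!is.null(force)) force
  else if (needs_firth(y, strata)) "Firth" else "ML"
  fit <- withCallingHandlers(
    fit_logistic(x, y, method = use),
    warning = function(w) {
      if (grepl("separation|singular", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (is.null(force) && use == "ML" &&
      (fit$separation_detected || !fit$converged)) {
    fit <- fit_logistic(x, y, method = "Firth")
  }
  fit
}

#' Covariate-adjusted effect of an exposure on a binary outcome
#'
#' Fits one logistic model with the exposure plus the full predefined
#' covariate set and reports the exposure's adjusted odds ratio with a
#' Wald CI. Rows with a missing outcome (e.g. ineligible for a recovery
#' period, or lost to follow-up) are dropped and counted. The method is
#' chosen automatically: Firth penalization when events or non-events are
#' rare (< 8) or when ML detects separation, ML otherwise; an explicit
#' \code{method} overrides this.
#'
#' @param data analysis data frame (raw cohort merged with derived
#'   outcomes).
#' @param exposure name of the exposure column. A logical/binary column is
#'   reported as an OR for exposed vs unexposed; a continuous column
#'   (e.g. \code{tmt_mean}) is reported per 1-unit \emph{decrease} when
#'   \code{per_decrease = TRUE}.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names.
#' @param method \code{"auto"}, \code{"ML"} or \code{"Firth"}.
#' @param per_decrease report a continuous exposure per 1-unit decrease by
#'   negating its coefficient.
#' @return an \code{effect_estimate} with the underlying
#'   \code{logistic_fit} attached as \code{$fit} and \code{n_dropped}
#'   rows excluded.
#' @export
adjusted_effect <- function(data, exposure, outcome,
                            covariates = covariate_set(),
                            method = c("auto", "ML", "Firth"),
                            per_decrease = FALSE) {
  method <- match.arg(method)
  keep <- stats::complete.cases(data[c(exposure, outcome, covariates)])
  df <- data[keep, , drop = FALSE]
  y <- as.numeric(df[[outcome]])
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("outcome '", outcome, "' has fewer than 2 events or non-events; ",
         "use the Firth subgroup path on a larger stratum")
  }
  des <- logistic_design(df, c(exposure, covariates))
  fit <- fit_auto(des$x, y,
                  force = if (method == "auto") NULL else method)
  use <- fit$method
  term <- grep(paste0("^", exposure), fit$terms, value = TRUE)[1]
  i <- match(term, fit$terms)
  beta <- fit$beta[i]
  se <- fit$se[i]
  if (per_decrease) beta <- -beta
  zq <- qnorm(0.975)
  structure(list(
    or_point = unname(exp(beta)),
    ci_low = unname(exp(beta - zq * se)),
    ci_high = unname(exp(beta + zq * se)),
    p = unname(2 * pnorm(-abs(beta / se))),
    scale_note = if (per_decrease) {
      paste0("adjusted OR per 1-unit decrease in ", exposure)
    } else {
      paste0("adjusted OR, ", exposure, " = 1 vs 0")
    },
    method = use,
    fit = fit,
    n = fit$n,
    n_dropped = sum(!keep)
  ), class = "effect_estimate")
}

#' Effect-modification scan over binary modifiers
#'
#' For each modifier (e.g. an NIHSS item present/absent, or a lesion
#' location flag), fits one model with exposure, modifier, their product
#' term, and the covariates; reports stratum-specific exposure ORs derived
#' from the fitted coefficients and the Wald p-value of the product term.
#' Firth penalization is substituted when any exposure-by-modifier stratum
#' has fewer than 8 events or non-events, or when ML detects separation.
#' No multiplicity correction is applied (reported p-values are raw).
#'
#' @param data analysis data frame.
#' @param exposure,outcome column names (both binary).
#' @param modifiers character vector of binary modifier column names.
#' @param covariates covariate column names.
#' @return data frame, one row per modifier: \code{modifier}, \code{or_mod0},
#'   \code{or_mod1} (stratum-specific exposure ORs), \code{p_interaction},
#'   \code{method}, \code{skipped}, \code{reason}.
#' @export
interaction_scan <- function(data, exposure, outcome, modifiers,
                             covariates = covariate_set()) {
  rows <- lapply(modifiers, function(m) {
    base <- data.frame(modifier = m, or_mod0 = NA_real_, or_mod1 = NA_real_,
                       p_interaction = NA_real_, method = NA_character_,
                       skipped = TRUE, reason = "", stringsAsFactors = FALSE)
    keep <- stats::complete.cases(data[c(exposure, outcome, m, covariates)])
    df <- data[keep, , drop = FALSE]
    mod <- as.numeric(df[[m]])
    if (length(unique(mod)) < 2) {
      base$reason <- "modifier constant"
      return(base)
    }
    y <- as.numeric(df[[outcome]])
    x <- as.numeric(df[[exposure]])
    des <- logistic_design(df, c(exposure, covariates))
    X <- cbind(des$x, modifier = mod, interaction = x * mod)
    strata <- interaction(x, mod, drop = TRUE)
    fit <- fit_auto(X, y, strata)
    exp_term <- grep(paste0("^", exposure), colnames(des$x), value = TRUE)[1]
    bi <- match(c(exp_term, "interaction"), fit$terms)
    b_exp <- fit$beta[bi[1]]
    b_int <- fit$beta[bi[2]]
    se_int <- fit$se[bi[2]]
    base$or_mod0 <- unname(exp(b_exp))
    base$or_mod1 <- unname(exp(b_exp + b_int))
    base$p_interaction <- unname(2 * pnorm(-abs(b_int / se_int)))
    base$method <- fit$method
    base$skipped <- FALSE
    base
  })
  do.call(rbind, rows)
}
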