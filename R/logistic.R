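#' Maximum-likelihood and Firth-penalized logistic regression
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' (IRLS), either by plain maximum likelihood or with Firth's Jeffreys-prior
#' score modification. The Firth variant keeps estimates finite under
#' complete or quasi-complete separation, which arises routinely in
#' rare-event subgroup and region-of-interest models.
#'
#' Convergence is declared when the maximum absolute component of the
#' (modified) score drops below \code{tol}. Under maximum likelihood,
#' separation is flagged when the coefficient of any non-constant column
#' exceeds \code{divergence_bound} in absolute value (the intercept is
#' exempt: with covariates on raw clinical scales its true value can be
#' large) or when the weighted information matrix becomes numerically
#' singular; the diverging fit is still returned (with a warning advising
#' the Firth method) so callers can inspect it.
#'
#' @param x numeric design matrix, one column per term, including the
#'   intercept column. Column names become coefficient names.
#' @param y binary response vector (0/1) of length \code{nrow(x)}.
#' @param method \code{"ML"} or \code{"Firth"}.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the maximum absolute score component.
#' @param divergence_bound coefficient bound (non-constant columns) beyond
#'   which an ML fit is declared separated.
#' @return an object of class \code{logistic_fit}: a list with
#'   \code{terms}, \code{beta}, \code{cov}, \code{se}, \code{method},
#'   \code{converged}, \code{iterations}, \code{loglik} (penalized
#'   log-likelihood for Firth), \code{separation_detected}, \code{n},
#'   \code{n_events}.
#' @examples
#' x <- cbind(1, c(0, 0, 1, 1, 0, 1))
#' colnames(x) <- c("(Intercept)", "exposure")
#' y <- c(0, 1, 1, 1, 0, 0)
#' fit_logistic(x, y, method = "ML")
#' @export
fit_logistic <- function(x, y, method = c("ML", "Firth"),
                         max_iter = 100L, tol = 1e-8,
                         divergence_bound = 15) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    stop("length(y) must equal nrow(x)")
  }
  if (anyNA(x) || anyNA(y)) {
    stop("fit_logistic does not accept missing values; drop or impute first")
  }
  if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary 0/1")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  # aliased columns are a caller bug for raw matrices; catch them up front
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[seq(qx$rank + 1L, ncol(x))]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }

  p_par <- ncol(x)
  col_sd <- apply(x, 2, sd)
  beta <- numeric(p_par)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  info <- NULL

  pen_loglik <- function(beta) {
    eta <- drop(x %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (method == "Firth") {
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      ll <- ll + 0.5 * determinant(crossprod(x, x * w))$modulus[1]
    }
    ll
  }

  ll_old <- pen_loglik(beta)
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(x, x * w)
    score <- drop(crossprod(x, y - mu))
    if (method == "Firth") {
      # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}, without the
      # n x n product: h_i = w_i x_i' (X'WX)^{-1} x_i
      h <- rowSums((x %*% solve(info)) * x) * w
      score <- drop(crossprod(x, y - mu + h * (0.5 - mu)))
    }
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) {
      if (method == "ML") {
        separated <- TRUE
        warning("information matrix singular under ML; ",
                "consider method = \"Firth\"", call. = FALSE)
      }
      break
    }
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- pen_loglik(beta_new)
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-10 || step < 1e-4)) break
      step <- step / 2
    }
    beta <- beta_new
    ll_old <- ll_new
    if (method == "ML" && any(col_sd > 0 & abs(beta) > divergence_bound)) {
      separated <- TRUE
      warning("apparent separation under ML (|beta| > ", divergence_bound,
              " for a non-constant column); consider method = \"Firth\"",
              call. = FALSE)
      break
    }
  }

  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(x, x * w)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p_par, p_par)
  })
  dimnames(cov) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)

  structure(list(
    terms = colnames(x),
    beta = beta,
    cov = cov,
    se = sqrt(pmax(diag(cov), 0)),
    method = method,
    converged = converged,
    iterations = iter,
    loglik = pen_loglik(beta),
    separation_detected = separated,
    n = nrow(x),
    n_events = sum(y)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (%s), n = %d, events = %d\n",
              x$method, x$n, x$n_events))
  z <- x$beta / x$se
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(
    beta = round(x$beta, 4), se = round(x$se, 4),
    OR = round(exp(x$beta), 3), p = signif(p, 3)
  )
  print(tab)
  if (!x$converged) cat("** did not converge in", x$iterations, "iterations\n")
  if (x$separation_detected) cat("** separation detected; use Firth\n")
  invisible(x)
}

#' Wald summary of a logistic fit
#'
#' @param fit a \code{logistic_fit}.
#' @param conf_level confidence level for Wald intervals.
#' @return data frame with one row per term: \code{term}, \code{beta},
#'   \code{se}, \code{or}, \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
fit_summary <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- fit$beta / fit$se
  data.frame(
    term = fit$terms,
    beta = unname(fit$beta),
    se = unname(fit$se),
    or = unname(exp(fit$beta)),
    ci_low = unname(exp(fit$beta - zq * fit$se)),
    ci_high = unname(exp(fit$beta + zq * fit$se)),
    p = unname(2 * pnorm(-abs(z))),
    row.names = NULL
  )
}

#' Build a logistic design matrix from a data frame
#'
#' Expands factors to reference-coded indicators (stroke subtype uses
#' large-artery atherosclerosis as the reference level), adds an intercept,
#' and drops aliased columns, reporting them.
#'
#' @param data data frame holding the predictors.
#' @param terms character vector of column names to include, in order.
#' @return list with \code{x} (design matrix) and \code{dropped}
#'   (character vector of aliased columns removed).
#' @export
logistic_design <- function(data, terms) {
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols)) {
    stop("missing predictor columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[terms]
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.logical(v)) v <- as.numeric(v)
    if (is.factor(v) && nm == "stroke_subtype") {
      v <- stats::relevel(factor(v), ref = "LAA")
    }
    if (is.factor(v) && nm == "sex") {
      v <- factor(v, levels = c("female", "male"))
    }
    df[[nm]] <- v
  }
  x <- stats::model.matrix(~ ., data = df)
  # drop aliased columns (e.g. a factor level absent from a subgroup)
  qx <- qr(x)
  dropped <- character(0)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(x)[-keep]
    x <- x[, sort(keep), drop = FALSE]
  }
  list(x = x, dropped = dropped)
}
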