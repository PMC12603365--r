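#' Published outcome contingency tables (low vs high TMT)
#'
#' The nine outcome-by-exposure 2x2 tables from the source registry study
#' of 600 elderly acute ischaemic stroke patients (151 low TMT, 449 high
#' TMT), with the period-specific eligibility exclusions already applied
#' (admission NIHSS 0 excluded for in-hospital recovery; discharge mRS 0/6
#' for post-discharge recovery; 3-month mRS 0/6 and 1-year follow-up loss
#' for chronic recovery and the 1-year mRS outcomes). These are inputs for
#' crude-effect reproduction and test fixtures; they are not computed here.
#'
#' @return named list of nine tables; each a list with counts \code{a}
#'   (low TMT, event), \code{b} (low TMT, no event), \code{c} (high TMT,
#'   event), \code{d} (high TMT, no event).
#' @examples
#' tab <- table_fixtures()$dysphagia
#' odds_ratio_2x2(tab$a, tab$b, tab$c, tab$d)
#' @export
table_fixtures <- function() {
  fix <- function(ev_low, n_low, ev_high, n_high) {
    list(a = ev_low, b = n_low - ev_low, c = ev_high, d = n_high - ev_high,
         n_low = n_low, n_high = n_high)
  }
  list(
    dysphagia              = fix(55, 151, 90, 449),
    end                    = fix(43, 151, 63, 449),
    inhosp_recovery        = fix(46, 138, 191, 410),
    postdischarge_recovery = fix(31, 139, 138, 400),
    chronic_recovery       = fix(30, 124, 101, 367),
    mrs3_ge3               = fix(91, 151, 150, 449),
    mrs3_ge4               = fix(56, 151, 61, 449),
    mrs1y_ge3              = fix(78, 140, 130, 440),
    mrs1y_ge4              = fix(50, 140, 67, 440)
  )
}

#' Crude-effects table from the published counts
#'
#' Recomputes, for each published 2x2 outcome table, the event percentage
#' in each TMT group and the univariable odds ratio with its Woolf 95\% CI
#' and Wald p-value.
#'
#' @param fixtures list of 2x2 tables as returned by
#'   \code{\link{table_fixtures}}.
#' @return data frame with one row per outcome: \code{outcome},
#'   \code{pct_low}, \code{pct_high}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}.
#' @export
crude_effects_table <- function(fixtures = table_fixtures()) {
  rows <- lapply(names(fixtures), function(nm) {
    f <- fixtures[[nm]]
    est <- odds_ratio_2x2(f$a, f$b, f$c, f$d)
    data.frame(outcome = nm,
               pct_low = 100 * f$a / f$n_low,
               pct_high = 100 * f$c / f$n_high,
               or = est$or_point, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
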