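#' @title Outcome derivation rules for the stroke cohort
#' @description Functions that turn raw registry records (TMT measurements,
#'   FOIS, serial NIHSS exams, mRS trajectory) into analysis-ready exposure
#'   and outcome flags under a fixed, documented rule set.
#' @name cohort-derivation
NULL

# NIHSS item names and legal maxima (items 1a-11)
NIHSS_ITEMS <- c(i1a = 3L, i1b = 2L, i1c = 2L, i2 = 2L, i3 = 3L, i4 = 3L,
                 i5a = 4L, i5b = 4L, i6a = 4L, i6b = 4L, i7 = 2L, i8 = 2L,
                 i9 = 3L, i10 = 2L, i11 = 2L)
NIHSS_CONSC <- c("i1a", "i1b", "i1c")
NIHSS_MOTOR <- c("i5a", "i5b", "i6a", "i6b")

#' Dichotomize temporal muscle thickness at the cohort 25th percentile
#'
#' The cutoff is the 25th percentile of the full analysis cohort, computed
#' with linear interpolation between order statistics
#' (\code{stats::quantile} type 7). Subjects strictly below the cutoff form
#' the low group; ties at the cutoff go to the high group.
#'
#' @param values positive numeric vector (mean TMT in mm, or TMT/height^2
#'   in mm/m^2) over the full analysis cohort.
#' @param variable label stored in the cutoff specification.
#' @param percentile percentile used as the cutoff (fixed design: 25).
#' @return list with \code{cutoff} (a \code{cutoff_spec}: variable,
#'   percentile, method, value) and \code{low} (logical vector).
#' @export
dichotomize_tmt <- function(values, variable = "tmt_mean", percentile = 25) {
  if (anyNA(values) || any(values <= 0)) {
    bad <- which(is.na(values) | values <= 0)
    stop("nonpositive or missing ", variable, " for subject index ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  cutoff <- unname(stats::quantile(values, percentile / 100, type = 7))
  list(
    cutoff = structure(list(variable = variable, percentile = percentile,
                            method = "linear_interpolation_type7",
                            value = cutoff),
                       class = "cutoff_spec"),
    low = values < cutoff
  )
}

#' Dysphagia from the Functional Oral Intake Scale
#'
#' FOIS 1-6 (tube dependence through restricted oral intake) counts as
#' dysphagia; 7 (total oral diet, no restriction) does not.
#'
#' @param fois integer vector with values in 1-7.
#' @return logical vector.
#' @export
derive_dysphagia <- function(fois) {
  if (anyNA(fois) || any(fois < 1 | fois > 7)) {
    stop("FOIS must be in 1-7")
  }
  fois <= 6
}

#' Early neurological deterioration from serial NIHSS exams
#'
#' END is any worsening within \code{window_days} of onset satisfying any
#' of: (i) total NIHSS increment >= 2; (ii) consciousness subscore (items
#' 1a-1c) increment >= 1; (iii) motor subscore (items 5a-6b) increment
#' >= 1; (iv) a clinically recorded new neurological deficit. END_4 is the
#' stricter total increment >= 4. Each increment is measured against the
#' running minimum of that quantity over all preceding exams (not only the
#' admission exam), so deterioration after early improvement is captured;
#' \code{reference = "admission"} switches to admission-only comparison.
#'
#' @param exams data frame of one subject's exams, time-sorted, with
#'   columns \code{t_days}, the items \code{i1a}..\code{i11} and
#'   \code{total}.
#' @param new_deficit logical; registry-recorded new neurological deficit
#'   within the window.
#' @param window_days observation window (days from onset).
#' @param reference \code{"running_min"} (default) or \code{"admission"}.
#' @return list with logicals \code{end}, \code{end4}, and
#'   \code{max_total_increment} (for END-cause validation).
#' @export
derive_end <- function(exams, new_deficit = FALSE, window_days = 21,
                       reference = c("running_min", "admission")) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(exams), nrow(exams) >= 1)
  if (is.unsorted(exams$t_days)) stop("exams must be time-sorted")
  in_window <- exams$t_days <= window_days
  if (!any(in_window)) {
    stop("no exam within the ", window_days, "-day window; END undefined")
  }
  ex <- exams[in_window, , drop = FALSE]
  total <- ex$total
  consc <- rowSums(ex[NIHSS_CONSC])
  motor <- rowSums(ex[NIHSS_MOTOR])

  max_inc <- function(v) {
    if (length(v) < 2) return(0)
    ref <- if (reference == "running_min") cummin(v)[-length(v)] else v[1]
    max(v[-1] - ref)
  }
  inc_total <- max_inc(total)
  end <- inc_total >= 2 || max_inc(consc) >= 1 || max_inc(motor) >= 1 ||
    isTRUE(new_deficit)
  list(end = end, end4 = inc_total >= 4, max_total_increment = inc_total)
}

#' Validate and pass through the END cause label
#'
#' The cause of END is a registry adjudication and is passed through
#' unchanged; subjects without END get \code{"none"}. A symptomatic
#' haemorrhagic transformation (sHT) label is checked against its defining
#' rule (total NIHSS increase >= 4); a discrepancy raises a warning but the
#' clinical label is kept.
#'
#' @param end_cause_label registry label: progression, recurrence, TIA,
#'   sHT, others, unknown, or none.
#' @param end logical END flag from \code{\link{derive_end}}.
#' @param max_total_increment maximum total NIHSS increment in the window.
#' @return character cause category.
#' @export
classify_end_cause <- function(end_cause_label, end, max_total_increment) {
  if (!end) return("none")
  if (identical(end_cause_label, "sHT") && max_total_increment < 4) {
    warning("sHT label without a >=4-point NIHSS increase (max increment ",
            max_total_increment, "); label kept", call. = FALSE)
  }
  if (is.na(end_cause_label) || end_cause_label == "none") "unknown"
  else end_cause_label
}

#' Period-specific recovery flags with eligibility
#'
#' Three recovery windows, each with its own eligibility rule:
#' \itemize{
#'   \item in-hospital: improvement of >= 4 points or >= 40\% in NIHSS from
#'     admission to discharge; subjects with admission NIHSS 0 are
#'     ineligible. The 40\% threshold is an exact rational comparison on
#'     the integer scores (\code{10 * delta >= 4 * admission}).
#'   \item post-discharge: 3-month mRS strictly below discharge mRS;
#'     ineligible when discharge mRS is 0 (asymptomatic) or 6 (dead).
#'   \item chronic: 1-year mRS strictly below 3-month mRS; ineligible when
#'     3-month mRS is 0 or 6, or the 1-year mRS is missing (lost to
#'     follow-up).
#' }
#'
#' @param nihss_admission,nihss_discharge integer NIHSS totals.
#' @param mrs_discharge,mrs_3mo,mrs_1y mRS values 0-6 (\code{mrs_1y} may be
#'   \code{NA}).
#' @return list of three elements (\code{inhosp}, \code{postdischarge},
#'   \code{chronic}), each a list with \code{eligible} (logical) and
#'   \code{recovered} (logical, \code{NA} when ineligible).
#' @export
derive_recovery <- function(nihss_admission, nihss_discharge,
                            mrs_discharge, mrs_3mo, mrs_1y = NA) {
  stopifnot(!is.na(nihss_admission), !is.na(nihss_discharge),
            !is.na(mrs_discharge), !is.na(mrs_3mo))
  inhosp <- if (nihss_admission == 0) {
    list(eligible = FALSE, recovered = NA)
  } else {
    delta <- nihss_admission - nihss_discharge
    list(eligible = TRUE,
         recovered = delta >= 4 || (10L * delta >= 4L * nihss_admission))
  }
  postd <- if (mrs_discharge %in% c(0L, 6L)) {
    list(eligible = FALSE, recovered = NA)
  } else {
    list(eligible = TRUE, recovered = mrs_3mo < mrs_discharge)
  }
  chronic <- if (mrs_3mo %in% c(0L, 6L) || is.na(mrs_1y)) {
    list(eligible = FALSE, recovered = NA)
  } else {
    list(eligible = TRUE, recovered = mrs_1y < mrs_3mo)
  }
  list(inhosp = inhosp, postdischarge = postd, chronic = chronic)
}

#' Median-impute missing infarct volume
#'
#' @param values numeric vector of infarct volume (\% of brain), possibly
#'   with missing entries.
#' @return list with \code{values} (imputed vector), \code{n_imputed}, and
#'   \code{median_used}.
#' @export
impute_infarct_volume <- function(values) {
  if (all(is.na(values))) stop("all infarct volumes missing; cannot impute")
  med <- stats::median(values, na.rm = TRUE)
  n_miss <- sum(is.na(values))
  values[is.na(values)] <- med
  list(values = values, n_imputed = n_miss, median_used = med)
}

#' Derive the full analysis table from raw records
#'
#' Applies every rule to a raw cohort: TMT averaging and 25th-percentile
#' dichotomization (also for TMT/height^2), dysphagia from FOIS, END/END_4
#' from serial NIHSS exams, END-cause validation, the three recovery flags
#' with eligibility, dichotomous mRS outcomes at 3 months and 1 year, and
#' median imputation of infarct volume. Admission/discharge NIHSS are the
#' first and last exam totals.
#'
#' @param cohort data frame of raw subject records (one row per subject),
#'   as produced by \code{\link{simulate_cohort}} or read from a registry
#'   export with the same columns.
#' @param nihss long-format data frame of serial exams (\code{subject_id},
#'   \code{t_days}, items, \code{total}).
#' @param window_days END observation window.
#' @param end_reference reference exam rule passed to \code{derive_end}.
#' @return data frame keyed by \code{subject_id} with the exposure and
#'   outcome columns, carrying attributes \code{cutoff_tmt},
#'   \code{cutoff_tmt_h2}, \code{exclusions} (eligibility tallies) and
#'   \code{n_imputed_infarct}.
#' @export
derive_outcomes <- function(cohort, nihss, window_days = 21,
                            end_reference = "running_min") {
  stopifnot(all(c("subject_id", "tmt_left", "tmt_right", "height_cm",
                  "fois", "mrs_discharge", "mrs_3mo") %in% names(cohort)))
  n <- nrow(cohort)
  tmt_mean <- (cohort$tmt_left + cohort$tmt_right) / 2
  tmt_h2 <- tmt_mean / (cohort$height_cm / 100)^2
  d_tmt <- dichotomize_tmt(tmt_mean, "tmt_mean")
  d_h2 <- dichotomize_tmt(tmt_h2, "tmt_h2")

  # vectorized pass over the long exam table (same rules as derive_end,
  # which remains the reference single-subject implementation)
  o <- order(nihss$subject_id, nihss$t_days)
  ns <- nihss[o, , drop = FALSE]
  item_mat <- as.matrix(ns[names(NIHSS_ITEMS)])
  consc_all <- rowSums(item_mat[, NIHSS_CONSC, drop = FALSE])
  motor_all <- rowSums(item_mat[, NIHSS_MOTOR, drop = FALSE])
  total_all <- ns$total
  tday_all <- ns$t_days
  idx <- split(seq_len(nrow(ns)), ns$subject_id)

  max_inc_vec <- function(v, reference) {
    if (length(v) < 2) return(0)
    ref <- if (reference == "running_min") cummin(v)[-length(v)] else v[1]
    max(v[-1] - ref)
  }
  end <- end4 <- logical(n)
  max_inc <- numeric(n)
  adm <- dis <- integer(n)
  for (i in seq_len(n)) {
    rows <- idx[[as.character(cohort$subject_id[i])]]
    if (is.null(rows) || !length(rows)) {
      stop("no NIHSS exams for subject ", cohort$subject_id[i])
    }
    inw <- rows[tday_all[rows] <= window_days]
    if (!length(inw)) {
      stop("no exam within the ", window_days, "-day window for subject ",
           cohort$subject_id[i])
    }
    it <- max_inc_vec(total_all[inw], end_reference)
    end[i] <- it >= 2 ||
      max_inc_vec(consc_all[inw], end_reference) >= 1 ||
      max_inc_vec(motor_all[inw], end_reference) >= 1 ||
      isTRUE(cohort$new_deficit_within_3w[i])
    end4[i] <- it >= 4
    max_inc[i] <- it
    adm[i] <- total_all[rows[1]]
    dis[i] <- total_all[rows[length(rows)]]
  }
  end_cause <- character(n)
  for (i in seq_len(n)) {
    end_cause[i] <- classify_end_cause(cohort$end_cause_label[i], end[i],
                                       max_inc[i])
  }

  rec <- lapply(seq_len(n), function(i) {
    derive_recovery(adm[i], dis[i], cohort$mrs_discharge[i],
                    cohort$mrs_3mo[i], cohort$mrs_1y[i])
  })
  pick <- function(period, field) {
    vapply(rec, function(r) {
      v <- r[[period]][[field]]
      if (is.na(v)) NA else as.logical(v)
    }, logical(1))
  }

  imp <- impute_infarct_volume(cohort$infarct_volume_pct)

  out <- data.frame(
    subject_id = cohort$subject_id,
    tmt_mean = tmt_mean,
    low_tmt = d_tmt$low,
    tmt_h2 = tmt_h2,
    low_tmt_h2 = d_h2$low,
    nihss_admission = adm,
    nihss_discharge = dis,
    dysphagia = derive_dysphagia(cohort$fois),
    end = end,
    end4 = end4,
    end_cause = end_cause,
    inhosp_eligible = pick("inhosp", "eligible"),
    inhosp_recovery = pick("inhosp", "recovered"),
    postdischarge_eligible = pick("postdischarge", "eligible"),
    postdischarge_recovery = pick("postdischarge", "recovered"),
    chronic_eligible = pick("chronic", "eligible"),
    chronic_recovery = pick("chronic", "recovered"),
    mrs3_ge3 = cohort$mrs_3mo >= 3,
    mrs3_ge4 = cohort$mrs_3mo >= 4,
    mrs1y_ge3 = ifelse(is.na(cohort$mrs_1y), NA, cohort$mrs_1y >= 3),
    mrs1y_ge4 = ifelse(is.na(cohort$mrs_1y), NA, cohort$mrs_1y >= 4),
    infarct_volume_pct_imputed = imp$values,
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff_tmt") <- d_tmt$cutoff
  attr(out, "cutoff_tmt_h2") <- d_h2$cutoff
  attr(out, "n_imputed_infarct") <- imp$n_imputed
  attr(out, "exclusions") <- list(
    inhosp_excluded_nihss0 = sum(!out$inhosp_eligible),
    postdischarge_excluded_mrs06 = sum(!out$postdischarge_eligible),
    chronic_excluded = sum(!out$chronic_eligible),
    lost_to_followup_1y = sum(is.na(cohort$mrs_1y))
  )
  out
}
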