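#' @title Synthetic stroke cohort generator
#' @description Generates cohorts of elderly acute-ischaemic-stroke records
#'   with the statistical structure the downstream analysis assumes:
#'   covariate marginals matching the registry's baseline table, TMT lower
#'   in women and decreasing with age, serial NIHSS trajectories into which
#'   early-neurological-deterioration events are injected, mRS trajectories
#'   consistent with planted recovery and outcome effects, and a planted
#'   mediation structure. Every effect is a named log-odds coefficient that
#'   can be zeroed or changed, so parameter-recovery and null tests are
#'   well-posed.
#' @name synthetic-cohort
NULL

# deterministic per-stream substreams derived from one global seed, so that
# changing e.g. the lesion stage never perturbs covariate draws; two Lehmer
# rounds around the stream offset mix seed and stream thoroughly (all
# intermediate products stay below 2^53, so double arithmetic is exact)
substream_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483646) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + stream * 452807053) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

#' Default planted log-odds effects
#'
#' Exposure (low TMT) effects on mediators and outcomes default to the
#' registry study's adjusted odds ratios (dysphagia 1.89, END 2.75,
#' in-hospital recovery 0.67, post-discharge recovery 0.56, chronic
#' recovery 1.13); mediator-to-outcome and direct-effect coefficients are
#' fixed design choices producing a partially mediated exposure effect on
#' the 3-month poor-outcome flag. \code{roi_interaction} is an empty named
#' vector (no lesion-location effect modification) by default.
#'
#' @return named list of log-odds coefficients.
#' @export
default_effect_sizes <- function() {
  list(
    exposure_dysphagia = log(1.89),
    exposure_end       = log(2.75),
    exposure_inhosp    = log(0.67),
    exposure_postdis   = log(0.56),
    exposure_chronic   = log(1.13),
    exposure_mrs3_direct = log(1.8),
    med_dysphagia_mrs3 = log(1.9),
    med_end_mrs3       = log(2.5),
    med_postdis_mrs3   = log(0.35),
    lesion_total_mrs3  = 0.3,          # per % of brain lesioned
    roi_lesion_mrs3    = numeric(0),   # named by ROI, per % of brain
    roi_interaction    = numeric(0)    # named by ROI; extra exposure effect
  )
}

default_covariate_params <- function() {
  list(
    p_male = 0.505,
    age_mean = 75.3, age_sd = 6.1, age_min = 65, age_max = 97,
    height_mean_male = 165.3, height_mean_female = 152.6, height_sd = 6.0,
    bmi_mean = 23.9, bmi_sd = 3.3,
    tmt_intercept = 5.99, tmt_male = 1.40, tmt_age_slope = -0.06,
    tmt_sd = 1.95, tmt_side_sd = 0.5, tmt_min = 1,
    p_pre_mrs1 = 0.12,
    p_prev_stroke = 0.198, p_hypertension = 0.827, p_diabetes = 0.447,
    p_hyperlipidaemia = 0.522, p_smoking_male = 0.70,
    p_smoking_female = 0.165, p_af = 0.233, p_cad = 0.095,
    subtype_probs = c(LAA = 0.352, SVO = 0.253, CE = 0.183,
                      undetermined = 0.2085, other = 0.0035),
    p_revascularization = 0.103,
    hb_male = 14.3, hb_female = 12.5, hb_sd = 1.55,
    chol_mean = 170.3, chol_sd = 39.3,
    albumin_mean = 4.2, albumin_sd = 0.4,
    nihss_size = 1.6, nihss_mu = 4.5, nihss_tmt_slope = -0.08,
    infarct_meanlog = log(0.07), infarct_sdlog = 1.13,
    infarct_nihss_slope = 0.08, p_infarct_missing = 2 / 600,
    p_death_discharge = 0.008, p_death_3mo = 0.02,
    base_rate_dysphagia = 0.185, base_rate_end = 0.135,
    base_rate_inhosp = 0.47, base_rate_postdis = 0.345,
    base_rate_chronic = 0.27, base_rate_mrs3 = 0.20
  )
}

default_lesion_params <- function() {
  list(dim = c(20L, 20L, 20L), voxel_volume_mm3 = 1,
       size_meanlog = log(6), size_sdlog = 1.1, size_max = 600)
}

#' Build and validate a simulation configuration
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer global seed; expanded internally into independent
#'   substreams for covariates, outcomes, and lesions.
#' @param effect_sizes named list overriding entries of
#'   \code{\link{default_effect_sizes}}.
#' @param covariate_params named list overriding baseline-distribution
#'   defaults (means, SDs, proportions).
#' @param lesion_params named list overriding the toy-template defaults
#'   (grid \code{dim}, \code{voxel_volume_mm3}, blob size distribution).
#' @param followup_loss_rate_1y proportion lost to 1-year follow-up.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects, seed = 1L, effect_sizes = list(),
                       covariate_params = list(), lesion_params = list(),
                       followup_loss_rate_1y = 20 / 580) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 ||
      is.na(n_subjects) || n_subjects < 1) {
    stop("invalid config field 'n_subjects': must be a positive integer")
  }
  es <- utils::modifyList(default_effect_sizes(), effect_sizes)
  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  lp <- utils::modifyList(default_lesion_params(), lesion_params)
  props <- c(cp$p_male, cp$p_pre_mrs1, cp$p_prev_stroke, cp$p_hypertension,
             cp$p_diabetes, cp$p_hyperlipidaemia, cp$p_smoking_male,
             cp$p_smoking_female, cp$p_af, cp$p_cad, cp$p_revascularization,
             cp$p_infarct_missing, followup_loss_rate_1y)
  if (any(props < 0 | props > 1)) {
    stop("invalid config field: a proportion lies outside [0, 1]")
  }
  sds <- c(cp$age_sd, cp$height_sd, cp$bmi_sd, cp$tmt_sd, cp$hb_sd,
           cp$chol_sd, cp$albumin_sd)
  if (any(sds <= 0)) stop("invalid config field: SDs must be > 0")
  if (length(lp$dim) != 3 || any(lp$dim < 8)) {
    stop("invalid config field 'lesion_params$dim': need >= 8 per axis")
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 effect_sizes = es, covariate_params = cp,
                 lesion_params = lp,
                 followup_loss_rate_1y = followup_loss_rate_1y),
            class = "sim_config")
}

# safe length-1 sampling (sample(5:5, 1) would draw from 1:5)
sample1 <- function(v) v[sample.int(length(v), 1)]

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# allocate integer NIHSS totals over items, motor-weighted, capped at the
# per-item maxima; returns n x 15 integer matrix (totals then = row sums)
allocate_nihss_items <- function(totals) {
  n <- length(totals)
  items <- matrix(0L, n, length(NIHSS_ITEMS),
                  dimnames = list(NULL, names(NIHSS_ITEMS)))
  wts <- c(i1a = 1, i1b = 1, i1c = 1, i2 = 1.5, i3 = 2, i4 = 3, i5a = 5,
           i5b = 5, i6a = 4, i6b = 4, i7 = 1, i8 = 2, i9 = 2, i10 = 3,
           i11 = 1.5)
  subj <- rep.int(seq_len(n), totals)
  if (length(subj)) {
    pick <- sample.int(length(NIHSS_ITEMS), length(subj), replace = TRUE,
                       prob = wts)
    tab <- table(factor(subj, levels = seq_len(n)),
                 factor(pick, levels = seq_along(NIHSS_ITEMS)))
    items <- matrix(as.integer(tab), n, length(NIHSS_ITEMS),
                    dimnames = list(NULL, names(NIHSS_ITEMS)))
    items <- pmin(items, matrix(NIHSS_ITEMS, n, length(NIHSS_ITEMS),
                                byrow = TRUE))
  }
  items
}

# remove k points from a subject's item vector (never below 0)
decrement_items <- function(items, k) {
  if (k <= 0) return(items)
  pool <- rep.int(seq_along(items), items)
  if (k >= length(pool)) return(items * 0L)
  take <- pool[sample.int(length(pool), k)]
  items - tabulate(take, nbins = length(items))
}

# add k points, respecting maxima; restrict to a subset of items if given,
# spilling to the remaining items only when the subset is saturated
increment_items <- function(items, k, subset = names(NIHSS_ITEMS)) {
  if (k <= 0) return(items)
  room <- pmax(NIHSS_ITEMS - items, 0L)
  in_sub <- names(NIHSS_ITEMS) %in% subset
  pool <- rep.int(which(in_sub), room[in_sub])
  if (length(pool) < k) {
    pool <- c(pool, rep.int(which(!in_sub), room[!in_sub]))
  }
  k <- min(k, length(pool))
  if (k == 0) return(items)
  take <- pool[sample.int(length(pool), k)]
  items + tabulate(take, nbins = length(items))
}

#' Simulate a cohort of raw patient records
#'
#' Draws covariates from the configured marginals (TMT as a linear model
#' in sex and age with Gaussian noise, truncated at 1 mm), dichotomizes
#' TMT at the cohort 25th percentile to obtain the exposure, then draws
#' mediators and outcomes from logistic models with the configured
#' log-odds effects. END events are injected into otherwise non-worsening
#' serial NIHSS trajectories (exam days 0, 2, 5, 10), so the derived END
#' flag equals the planted one; mRS trajectories are constructed to agree
#' with the planted recovery and poor-outcome draws wherever the ordinal
#' constraints permit.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohort} (one row per subject) and \code{nihss}
#'   (long-format serial exams: \code{subject_id}, \code{t_days}, items,
#'   \code{total}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  cp <- config$covariate_params
  es <- config$effect_sizes

  ## ---- covariate stream ----
  set.seed(substream_seed(config$seed, 1L))
  male <- rbinom(n, 1, cp$p_male)
  age <- rtrunc_norm(n, cp$age_mean, cp$age_sd, cp$age_min, cp$age_max)
  height <- rnorm(n, ifelse(male == 1, cp$height_mean_male,
                            cp$height_mean_female), cp$height_sd)
  bmi <- rtrunc_norm(n, cp$bmi_mean, cp$bmi_sd, 14, 45)
  weight <- bmi * (height / 100)^2
  tmt <- cp$tmt_intercept + cp$tmt_male * male +
    cp$tmt_age_slope * (age - cp$age_mean) + rnorm(n, 0, cp$tmt_sd)
  tmt <- pmax(tmt, cp$tmt_min)
  side <- rnorm(n, 0.1, cp$tmt_side_sd)
  tmt_right <- pmax(tmt + side / 2, 0.5)
  tmt_left <- pmax(tmt - side / 2, 0.5)
  tmt_mean <- (tmt_left + tmt_right) / 2
  pre_mrs <- rbinom(n, 1, cp$p_pre_mrs1)
  prev_stroke <- rbinom(n, 1, cp$p_prev_stroke)
  hypertension <- rbinom(n, 1, cp$p_hypertension)
  diabetes <- rbinom(n, 1, cp$p_diabetes)
  hyperlipidaemia <- rbinom(n, 1, cp$p_hyperlipidaemia)
  smoking <- rbinom(n, 1, ifelse(male == 1, cp$p_smoking_male,
                                 cp$p_smoking_female))
  atrial_fibrillation <- rbinom(n, 1, cp$p_af)
  coronary_artery_disease <- rbinom(n, 1, cp$p_cad)
  stroke_subtype <- sample(names(cp$subtype_probs), n, replace = TRUE,
                           prob = cp$subtype_probs)
  revascularization <- rbinom(n, 1, cp$p_revascularization)
  haemoglobin <- rnorm(n, ifelse(male == 1, cp$hb_male, cp$hb_female),
                       cp$hb_sd)
  total_cholesterol <- rtrunc_norm(n, cp$chol_mean, cp$chol_sd, 60, 400)
  albumin <- rtrunc_norm(n, cp$albumin_mean, cp$albumin_sd, 2, 6)
  nihss_mu <- cp$nihss_mu * exp(cp$nihss_tmt_slope * (tmt_mean - 6.7))
  nihss_draw <- rnbinom(n, size = cp$nihss_size, mu = nihss_mu)
  nihss_draw <- pmin(nihss_draw, 30L)
  infarct <- exp(rnorm(n, cp$infarct_meanlog +
                         cp$infarct_nihss_slope * (pmin(nihss_draw, 15) - 4),
                       cp$infarct_sdlog))
  infarct <- pmin(infarct, 50)
  infarct[runif(n) < cp$p_infarct_missing] <- NA

  low_tmt <- dichotomize_tmt(tmt_mean)$low

  ## ---- outcome stream ----
  set.seed(substream_seed(config$seed, 2L))
  znihss <- (nihss_draw - 4.5) / 4
  zage <- (age - cp$age_mean) / cp$age_sd
  zvol <- log1p(ifelse(is.na(infarct), 0.07, infarct))

  dysphagia <- rbinom(n, 1, plogis(qlogis(cp$base_rate_dysphagia) +
    es$exposure_dysphagia * low_tmt + 0.45 * znihss + 0.25 * zage)) == 1
  fois <- ifelse(dysphagia, sample(1:6, n, replace = TRUE,
                                   prob = c(1, 1, 2, 3, 4, 5)), 7L)

  end_flag <- rbinom(n, 1, plogis(qlogis(cp$base_rate_end) +
    es$exposure_end * low_tmt + 0.5 * znihss + 0.2 * zage +
    0.25 * zvol)) == 1

  # END mechanism: criterion path and cause, per-registry mix
  end_type <- rep("none", n)
  end_type[end_flag] <- sample(
    c("total", "motor", "consciousness", "new_deficit"),
    sum(end_flag), replace = TRUE, prob = c(0.55, 0.20, 0.10, 0.15))
  end_cause_label <- rep("none", n)
  end_cause_label[end_flag] <- sample(
    c("progression", "recurrence", "sHT", "others", "unknown", "TIA"),
    sum(end_flag), replace = TRUE,
    prob = c(0.78, 0.03, 0.05, 0.04, 0.09, 0.01))
  # sHT is defined by a >=4-point total rise; force the matching mechanism
  end_type[end_cause_label == "sHT"] <- "total"
  new_deficit <- end_flag & (end_type == "new_deficit" | runif(n) < 0.05)

  inhosp_intent <- rbinom(n, 1, plogis(qlogis(cp$base_rate_inhosp) +
    es$exposure_inhosp * low_tmt + 0.2 * znihss - 0.2 * zage +
    0.8 * revascularization)) == 1
  postdis_intent <- rbinom(n, 1, plogis(qlogis(cp$base_rate_postdis) +
    es$exposure_postdis * low_tmt - 0.15 * zage)) == 1
  chronic_intent <- rbinom(n, 1, plogis(qlogis(cp$base_rate_chronic) +
    es$exposure_chronic * low_tmt - 0.1 * zage)) == 1

  ## serial NIHSS trajectories (days 0, 2, 5, 10)
  adm_items <- allocate_nihss_items(nihss_draw)
  adm_total <- as.integer(rowSums(adm_items))
  # discharge improvement target from the in-hospital recovery intent
  s_target <- integer(n)
  for (i in seq_len(n)) {
    a <- adm_total[i]
    if (a == 0) next
    if (inhosp_intent[i]) {
      s_target[i] <- min(a, max(4L, as.integer(ceiling(0.4 * a))))
    } else {
      smax <- min(3L, as.integer(ceiling(0.4 * a)) - 1L)
      s_target[i] <- if (smax >= 1) sample(0:smax, 1) else 0L
    }
  }
  t_days <- c(0, 2, 5, 10)
  TR <- matrix(0L, 4L * n, length(NIHSS_ITEMS),
               dimnames = list(NULL, names(NIHSS_ITEMS)))
  end4 <- logical(n)
  for (i in seq_len(n)) {
    drops <- c(0L, as.integer(round(s_target[i] * c(0.3, 0.7, 1))))
    traj <- matrix(0L, 4, length(NIHSS_ITEMS),
                   dimnames = list(NULL, names(NIHSS_ITEMS)))
    traj[1, ] <- adm_items[i, ]
    # nested decline: items are monotone non-increasing, so non-END
    # subjects can never trip an increment criterion by item shuffling
    for (k in 2:4) {
      traj[k, ] <- decrement_items(traj[k - 1, ], drops[k] - drops[k - 1])
    }
    if (end_flag[i] && end_type[i] != "new_deficit") {
      j <- sample1(2:3)  # worsen at day 2 or 5
      persist <- runif(1) < 0.5
      rows <- if (persist) j:4 else j
      if (end_type[i] == "total") {
        target <- if (end_cause_label[i] == "sHT" || runif(1) < 0.45) {
          sample1(4:8)
        } else sample1(2:3)
        # plant the rise against the realized running minimum
        prev_min <- min(rowSums(traj[seq_len(j - 1), , drop = FALSE]))
        for (k in rows) {
          add <- prev_min + target - sum(traj[k, ])
          if (add > 0) traj[k, ] <- increment_items(traj[k, ], add)
        }
      } else {
        sub <- if (end_type[i] == "motor") NIHSS_MOTOR else NIHSS_CONSC
        prev_min <- min(rowSums(traj[seq_len(j - 1), sub, drop = FALSE]))
        for (k in rows) {
          add <- prev_min + 1L - sum(traj[k, sub])
          if (add > 0) traj[k, ] <- increment_items(traj[k, ], add, sub)
        }
      }
    }
    totals <- as.integer(rowSums(traj))
    end4[i] <- any(totals[-1] - cummin(totals)[-4] >= 4)
    TR[(i - 1L) * 4L + 1:4, ] <- traj
  }
  all_totals <- as.integer(rowSums(TR))
  nihss_long <- data.frame(subject_id = rep(seq_len(n), each = 4L),
                           t_days = rep(t_days, n), TR,
                           total = all_totals)
  dis_total <- all_totals[seq_len(n) * 4L]

  ## mRS trajectory construction
  mrs_out <- build_mrs_trajectory(
    n = n, dis_total = dis_total, low_tmt = low_tmt,
    dysphagia = dysphagia, end_flag = end_flag,
    postdis_intent = postdis_intent, chronic_intent = chronic_intent,
    znihss = znihss, zage = zage, es = es, cp = cp,
    followup_loss_rate_1y = config$followup_loss_rate_1y)

  cohort <- data.frame(
    subject_id = seq_len(n),
    age = age, sex = ifelse(male == 1, "male", "female"),
    height_cm = height, weight_kg = weight, bmi = bmi,
    tmt_left = tmt_left, tmt_right = tmt_right,
    pre_mrs = pre_mrs, prev_stroke = prev_stroke,
    hypertension = hypertension, diabetes = diabetes,
    hyperlipidaemia = hyperlipidaemia, smoking = smoking,
    atrial_fibrillation = atrial_fibrillation,
    coronary_artery_disease = coronary_artery_disease,
    stroke_subtype = stroke_subtype,
    revascularization = revascularization,
    haemoglobin = haemoglobin, total_cholesterol = total_cholesterol,
    albumin = albumin, fois = as.integer(fois),
    mrs_discharge = mrs_out$mrs_discharge, mrs_3mo = mrs_out$mrs_3mo,
    mrs_1y = mrs_out$mrs_1y,
    new_deficit_within_3w = new_deficit,
    end_cause_label = end_cause_label,
    infarct_volume_pct = infarct,
    lesion_mask_ref = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(cohort, "planted") <- list(
    low_tmt = low_tmt, dysphagia = dysphagia, end = end_flag, end4 = end4,
    inhosp_intent = inhosp_intent, postdis_intent = postdis_intent,
    chronic_intent = chronic_intent, mrs3_poor = mrs_out$y3)
  list(cohort = cohort, nihss = nihss_long)
}

# construct discharge / 3-month / 1-year mRS consistent with the planted
# recovery intents and the logistic poor-outcome draw; on the impossible
# combinations (e.g. recovery from discharge mRS <= 3 while staying >= 3)
# the poor-outcome draw wins and the recovery intent flips, so the planted
# outcome effects stay clean while recovery effects attenuate slightly;
# death is absorbing
build_mrs_trajectory <- function(n, dis_total, low_tmt, dysphagia, end_flag,
                                 postdis_intent, chronic_intent,
                                 znihss, zage, es, cp,
                                 followup_loss_rate_1y, y3 = NULL) {
  mrs_discharge <- as.integer(cut(dis_total, c(-1, 0, 2, 5, 9, 15, 42))) - 1L
  jit <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.15, 0.7, 0.15))
  mrs_discharge <- pmin(pmax(mrs_discharge + jit, 0L), 5L)
  mrs_discharge[runif(n) < cp$p_death_discharge] <- 6L

  if (is.null(y3)) {
    y3 <- rbinom(n, 1, plogis(qlogis(cp$base_rate_mrs3) +
      es$exposure_mrs3_direct * low_tmt +
      es$med_dysphagia_mrs3 * dysphagia +
      es$med_end_mrs3 * end_flag +
      es$med_postdis_mrs3 * postdis_intent +
      0.9 * znihss + 0.35 * zage)) == 1
  }

  mrs_3mo <- integer(n)
  for (i in seq_len(n)) {
    d <- mrs_discharge[i]
    if (d == 6L) { mrs_3mo[i] <- 6L; next }
    if (d == 0L) {
      mrs_3mo[i] <- if (y3[i]) sample1(3:5) else
        if (runif(1) < 0.8) 0L else sample1(1:2)
      next
    }
    rec <- postdis_intent[i]
    if (rec) {
      mrs_3mo[i] <- if (y3[i] && d >= 4L) {
        sample1(3:(d - 1L))
      } else if (y3[i]) {
        sample1(max(3L, d):5L)            # conflict: outcome wins, no recovery
      } else sample1(0:min(2L, d - 1L))
    } else {
      mrs_3mo[i] <- if (y3[i]) {
        sample1(max(3L, d):5L)
      } else if (d <= 2L) sample1(d:2L)
      else sample1(0:2L)                  # conflict: outcome wins, recovery
    }
  }
  died_3mo <- mrs_discharge < 6L & runif(n) < cp$p_death_3mo
  mrs_3mo[died_3mo] <- 6L

  mrs_1y <- integer(n)
  for (i in seq_len(n)) {
    m3 <- mrs_3mo[i]
    if (m3 == 6L) { mrs_1y[i] <- 6L; next }
    if (m3 == 0L) {
      mrs_1y[i] <- if (runif(1) < 0.85) 0L else 1L
      next
    }
    if (chronic_intent[i]) {
      mrs_1y[i] <- m3 - 1L
    } else {
      up <- sample1(c(0L, 0L, 0L, 1L))
      mrs_1y[i] <- min(m3 + up, 5L)
      if (m3 >= 3L && runif(1) < 0.05) mrs_1y[i] <- 6L
    }
  }
  mrs_1y[runif(n) < followup_loss_rate_1y] <- NA_integer_

  list(mrs_discharge = mrs_discharge, mrs_3mo = mrs_3mo, mrs_1y = mrs_1y,
       y3 = y3)
}
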