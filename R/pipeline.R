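#' Merge raw records with derived outcomes into the analysis table
#'
#' @param cohort raw cohort data frame.
#' @param nihss long-format serial NIHSS exams.
#' @param ... passed to \code{\link{derive_outcomes}}.
#' @return merged data frame (raw columns plus derived flags), carrying
#'   the derivation attributes (\code{cutoff_tmt}, \code{exclusions},
#'   \code{n_imputed_infarct}).
#' @export
analysis_table <- function(cohort, nihss, ...) {
  der <- derive_outcomes(cohort, nihss, ...)
  out <- merge(cohort, der, by = "subject_id", sort = TRUE)
  out <- out[order(out$subject_id), , drop = FALSE]
  for (a in c("cutoff_tmt", "cutoff_tmt_h2", "exclusions",
              "n_imputed_infarct")) {
    attr(out, a) <- attr(der, a)
  }
  out
}

#' Presenting-symptom modifier flags from admission NIHSS items
#'
#' Symptom present means the admission score of the item (or item group)
#' is >= 1: motor deficit (items 5a-6b), facial palsy (item 4),
#' dysarthria (item 10), reduced consciousness (items 1a-1c).
#'
#' @param nihss long-format serial exams.
#' @return data frame: \code{subject_id} plus logical modifier columns.
#' @export
derive_modifiers <- function(nihss) {
  first <- nihss[!duplicated(nihss$subject_id), , drop = FALSE]
  data.frame(
    subject_id = first$subject_id,
    motor_deficit = rowSums(first[NIHSS_MOTOR]) >= 1,
    facial_palsy = first$i4 >= 1,
    dysarthria = first$i10 >= 1,
    reduced_consciousness = rowSums(first[NIHSS_CONSC]) >= 1
  )
}

#' Write / read the cohort in its CSV exchange format
#'
#' One row per subject, with serial NIHSS exams in a long-format companion
#' CSV keyed by \code{subject_id} and \code{t_days}.
#'
#' @param sim list with \code{cohort} and \code{nihss}.
#' @param dir directory for \code{cohort.csv} and \code{nihss.csv}.
#' @return invisibly, the file paths (write) or the list (read).
#' @export
write_cohort_csv <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- file.path(dir, "cohort.csv")
  pn <- file.path(dir, "nihss.csv")
  utils::write.csv(sim$cohort, pc, row.names = FALSE)
  utils::write.csv(sim$nihss, pn, row.names = FALSE)
  invisible(c(pc, pn))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  list(cohort = utils::read.csv(file.path(dir, "cohort.csv"),
                                stringsAsFactors = FALSE),
       nihss = utils::read.csv(file.path(dir, "nihss.csv"),
                               stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, derives outcomes, and runs the
#' enabled stages: crude effects (published-table analogue), adjusted
#' effects for every outcome, presenting-symptom interaction scans,
#' mediation of the 3-month poor-outcome effect, ROI-wise brain mapping
#' with symmetric pooling, and sensitivity analyses (continuous TMT per
#' 1 mm decrease; TMT/height^2 dichotomized at its 25th percentile).
#' Writes tidy CSV tables and a machine-readable JSON manifest (inputs,
#' cutoffs, exclusion tallies, seed) to \code{out_dir}.
#'
#' @param config a \code{\link{sim_config}}; or a list with \code{cohort}
#'   and \code{nihss} data frames for real data.
#' @param out_dir output directory; \code{NULL} skips writing.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("crude", "adjusted", "scan", "mediation", "mapping",
#'   "sensitivity")}.
#' @param n_boot bootstrap replicates for the mediation stage.
#' @return list of stage results plus the \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("crude", "adjusted", "scan",
                                    "mediation", "mapping", "sensitivity"),
                         n_boot = 200) {
  if (inherits(config, "sim_config")) {
    sim <- if ("mapping" %in% stages) simulate_study(config) else
      simulate_cohort(config)
    seed <- config$seed
  } else {
    sim <- config
    seed <- if (!is.null(config$seed)) config$seed else 1L
  }
  dat <- analysis_table(sim$cohort, sim$nihss)
  results <- list()
  manifest <- list(
    seed = seed,
    n_subjects = nrow(dat),
    stages = stages,
    cutoff_tmt = attr(dat, "cutoff_tmt"),
    cutoff_tmt_h2 = attr(dat, "cutoff_tmt_h2"),
    exclusions = attr(dat, "exclusions"),
    n_imputed_infarct = attr(dat, "n_imputed_infarct")
  )

  outcomes <- c("dysphagia", "end", "inhosp_recovery",
                "postdischarge_recovery", "chronic_recovery",
                "mrs3_ge3", "mrs3_ge4", "mrs1y_ge3", "mrs1y_ge4")

  if ("crude" %in% stages) {
    rows <- lapply(outcomes, function(o) {
      y <- dat[[o]]
      keep <- !is.na(y)
      a <- sum(y[keep] & dat$low_tmt[keep])
      b <- sum(!y[keep] & dat$low_tmt[keep])
      cc <- sum(y[keep] & !dat$low_tmt[keep])
      d <- sum(!y[keep] & !dat$low_tmt[keep])
      est <- odds_ratio_2x2(a, b, cc, d)
      cmp <- compare_groups(y[keep], dat$low_tmt[keep])
      data.frame(outcome = o, a = a, b = b, c = cc, d = d,
                 n = sum(keep), or = est$or_point, ci_low = est$ci_low,
                 ci_high = est$ci_high, p = est$p, test = cmp$test,
                 p_group = cmp$p, stringsAsFactors = FALSE)
    })
    results$crude <- do.call(rbind, rows)
  }

  if ("adjusted" %in% stages) {
    rows <- lapply(outcomes, function(o) {
      est <- tryCatch(adjusted_effect(dat, "low_tmt", o),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      data.frame(outcome = o, aor = est$or_point, ci_low = est$ci_low,
                 ci_high = est$ci_high, p = est$p, method = est$method,
                 n = est$n, stringsAsFactors = FALSE)
    })
    results$adjusted <- do.call(rbind, rows)
  }

  if ("scan" %in% stages) {
    mods <- derive_modifiers(sim$nihss)
    dm <- merge(dat, mods, by = "subject_id", sort = TRUE)
    results$scan <- interaction_scan(
      dm, "low_tmt", "mrs3_ge3",
      c("motor_deficit", "facial_palsy", "dysarthria",
        "reduced_consciousness"))
  }

  if ("mediation" %in% stages) {
    screen <- mediator_entry_screen(
      dat, c("dysphagia", "end", "postdischarge_recovery"),
      "low_tmt", "mrs3_ge3")
    admitted <- screen$candidate[screen$admitted]
    results$mediator_screen <- screen
    if (length(admitted)) {
      results$mediation <- mediate(dat, "low_tmt", "mrs3_ge3", admitted,
                                   n_boot = n_boot, seed = seed)
    }
  }

  if ("mapping" %in% stages && !is.null(sim$burden)) {
    results$mapping <- map_interactions(dat, sim$burden, "mrs3_ge3")
    pooled <- pool_symmetric(sim$burden)
    results$mapping_pooled <- map_interactions(dat, pooled, "mrs3_ge3")
  }

  if ("sensitivity" %in% stages) {
    rows <- lapply(outcomes, function(o) {
      cont <- tryCatch(adjusted_effect(dat, "tmt_mean", o,
                                       per_decrease = TRUE),
                       error = function(e) NULL)
      h2 <- tryCatch(adjusted_effect(dat, "low_tmt_h2", o),
                     error = function(e) NULL)
      if (is.null(cont) || is.null(h2)) return(NULL)
      data.frame(outcome = o,
                 aor_per_mm_decrease = cont$or_point,
                 cont_ci_low = cont$ci_low, cont_ci_high = cont$ci_high,
                 cont_p = cont$p,
                 aor_low_tmt_h2 = h2$or_point, h2_ci_low = h2$ci_low,
                 h2_ci_high = h2$ci_high, h2_p = h2$p,
                 stringsAsFactors = FALSE)
    })
    results$sensitivity <- do.call(rbind, rows)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      if (is.data.frame(results[[nm]])) {
        utils::write.csv(results[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(results$mediation)) {
      m <- results$mediation
      jsonlite::write_json(
        list(total = m$total, direct = m$direct,
             indirect_combined = m$indirect_combined,
             indirect = as.list(m$indirect),
             proportion_mediated = m$proportion_mediated,
             ci_total = m$ci_total, ci_indirect = m$ci_indirect_combined,
             n = m$n, n_boot = m$n_boot),
        file.path(out_dir, "mediation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  results$manifest <- manifest
  results
}
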