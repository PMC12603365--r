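#' Merge atlases by priority
#'
#' Voxels claimed by more than one atlas are assigned the label of the
#' highest-priority atlas; unclaimed voxels stay unlabeled (0). Label
#' provenance (source atlas and hemisphere) is retained in the label
#' table.
#'
#' @param atlases named list of atlases (as from \code{\link{toy_atlases}}
#'   or read from NIfTI label volumes), each with \code{labels} (integer
#'   array) and \code{table} (\code{value}, \code{region},
#'   \code{hemisphere}).
#' @param priority character vector of atlas names, highest priority
#'   first; no duplicates.
#' @param voxel_volume_mm3 voxel volume shared by all volumes.
#' @param brain_mask logical array/vector of brain voxels; defaults to the
#'   whole grid.
#' @return an \code{atlas_set}: list with \code{merged} (integer array,
#'   sequential labels), \code{table} (\code{value}, \code{region},
#'   \code{atlas}, \code{hemisphere}), \code{priority},
#'   \code{voxel_volume_mm3}, \code{brain_mask}.
#' @export
merge_atlases <- function(atlases, priority = names(atlases),
                          voxel_volume_mm3 = 1, brain_mask = NULL) {
  if (anyDuplicated(priority)) stop("priority order has duplicate atlases")
  if (!all(priority %in% names(atlases))) {
    stop("priority names an atlas that was not supplied")
  }
  dims <- dim(atlases[[priority[1]]]$labels)
  for (nm in priority) {
    if (!identical(dim(atlases[[nm]]$labels), dims)) {
      stop("grid mismatch: atlas '", nm, "' is not on the shared grid")
    }
  }
  merged <- array(0L, dims)
  table <- data.frame(value = integer(0), region = character(0),
                      atlas = character(0), hemisphere = character(0),
                      stringsAsFactors = FALSE)
  next_val <- 1L
  # paint lowest priority first so higher priority overwrites
  for (nm in rev(priority)) {
    at <- atlases[[nm]]
    for (i in seq_len(nrow(at$table))) {
      v <- at$table$value[i]
      merged[at$labels == v] <- next_val
      table <- rbind(table, data.frame(
        value = next_val, region = at$table$region[i], atlas = nm,
        hemisphere = at$table$hemisphere[i], stringsAsFactors = FALSE))
      next_val <- next_val + 1L
    }
  }
  # drop labels fully overwritten by higher-priority atlases
  present <- sort(unique(as.integer(merged)))
  table <- table[table$value %in% present, , drop = FALSE]
  if (is.null(brain_mask)) brain_mask <- rep(TRUE, prod(dims))
  structure(list(merged = merged, table = table, priority = priority,
                 voxel_volume_mm3 = voxel_volume_mm3,
                 brain_mask = brain_mask, dim = dims),
            class = "atlas_set")
}

#' Per-subject, per-ROI lesion burden
#'
#' Burden of subject s in ROI r is the lesioned voxel volume inside r as a
#' percentage of total brain volume; the per-subject total uses the brain
#' mask. Row sums can be below the total because voxels outside every ROI
#' exist.
#'
#' @param lesions a \code{lesion_set} on the atlas grid.
#' @param atlas_set an \code{atlas_set}.
#' @return a \code{roi_burden} object: list with \code{burden} (numeric
#'   matrix, subjects x ROIs, columns named by region) and \code{total}
#'   (per-subject total lesion \%).
#' @export
roi_burden <- function(lesions, atlas_set) {
  if (!identical(as.integer(lesions$dim), as.integer(atlas_set$dim))) {
    stop("mask grid does not match the atlas grid")
  }
  n_brain <- sum(atlas_set$brain_mask)
  labs <- as.integer(atlas_set$merged)
  rois <- atlas_set$table$value
  n <- length(lesions$masks)
  burden <- matrix(0, n, length(rois),
                   dimnames = list(names(lesions$masks),
                                   atlas_set$table$region))
  for (i in seq_len(n)) {
    m <- lesions$masks[[i]]
    bad <- m < 1 | m > length(labs)
    if (any(bad)) {
      stop("mask off-grid for subject ", names(lesions$masks)[i])
    }
    if (!length(m)) next
    tab <- tabulate(labs[m], nbins = max(rois))
    burden[i, ] <- 100 * tab[rois] / n_brain
  }
  structure(list(burden = burden,
                 total = 100 * lengths(lesions$masks) / n_brain,
                 table = atlas_set$table),
            class = "roi_burden")
}

#' Default left/right pairing from the atlas label table
#'
#' Pairs regions whose names differ only by a \code{_L}/\code{_R} suffix;
#' midline regions (hemisphere \code{"M"}) map to themselves.
#'
#' @param atlas_set an \code{atlas_set}.
#' @return data frame with columns \code{left}, \code{right},
#'   \code{pooled} (canonical name).
#' @export
symmetric_pairing <- function(atlas_set) {
  tab <- atlas_set$table
  base <- sub("_(L|R)$", "", tab$region)
  out <- list()
  for (b in unique(base)) {
    rs <- tab$region[base == b]
    l <- rs[grepl("_L$", rs)][1]
    r <- rs[grepl("_R$", rs)][1]
    if (!is.na(l) && !is.na(r)) {
      out[[length(out) + 1]] <- data.frame(left = l, right = r, pooled = b,
                                           stringsAsFactors = FALSE)
    } else if (length(rs) == 1 && !grepl("_(L|R)$", rs)) {
      out[[length(out) + 1]] <- data.frame(left = rs, right = rs, pooled = rs,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pool left/right symmetric ROI burdens
#'
#' Pooled burden is the sum of the left and right entries per subject
#' (self-paired midline ROIs pass through unchanged), a pre-planned move
#' against small per-side lesion counts.
#'
#' @param burden a \code{roi_burden}.
#' @param pairing data frame with \code{left}, \code{right},
#'   \code{pooled}; defaults cover every pairable ROI in the burden's
#'   label table.
#' @return a \code{roi_burden} with pooled columns.
#' @export
pool_symmetric <- function(burden, pairing = NULL) {
  stopifnot(inherits(burden, "roi_burden"))
  if (is.null(pairing)) {
    pairing <- symmetric_pairing(structure(list(table = burden$table),
                                           class = "atlas_set"))
  }
  sides <- c(pairing$left, pairing$right[pairing$right != pairing$left])
  if (anyDuplicated(sides)) {
    stop("an ROI appears in two pairs: ",
         paste(unique(sides[duplicated(sides)]), collapse = ", "))
  }
  missing_rois <- setdiff(sides, colnames(burden$burden))
  if (length(missing_rois)) {
    stop("pairing references unknown ROIs: ",
         paste(missing_rois, collapse = ", "))
  }
  pooled <- sapply(seq_len(nrow(pairing)), function(i) {
    l <- burden$burden[, pairing$left[i]]
    if (pairing$left[i] == pairing$right[i]) l
    else l + burden$burden[, pairing$right[i]]
  })
  pooled <- matrix(pooled, nrow = nrow(burden$burden),
                   dimnames = list(rownames(burden$burden), pairing$pooled))
  structure(list(burden = pooled, total = burden$total,
                 table = data.frame(value = seq_len(ncol(pooled)),
                                    region = pairing$pooled,
                                    atlas = "pooled", hemisphere = "LR",
                                    stringsAsFactors = FALSE)),
            class = "roi_burden")
}

#' ROI-wise lesion-by-exposure interaction mapping
#'
#' One logistic model per ROI: outcome ~ ROI lesion burden + exposure +
#' burden-by-exposure product + the predefined covariates \emph{without}
#' total infarct volume (collinear with the per-ROI burden). Significance
#' is flagged at raw p-for-interaction < 0.05; no multiplicity correction
#' is applied. ROIs with no lesioned subject are skipped; ROIs with fewer
#' than 5 lesioned subjects are fitted with Firth penalization and flagged
#' low-support, as are models with rare events or ML separation.
#'
#' @param data analysis data frame with exposure, outcome, covariates;
#'   rows aligned with the burden matrix.
#' @param burden a \code{roi_burden}.
#' @param outcome,exposure column names in \code{data}.
#' @param covariates covariate columns; defaults to the predefined set
#'   minus total infarct volume.
#' @param alpha significance level for the flag.
#' @param rois ROI names to fit; default all columns of the burden matrix.
#' @return data frame, one row per ROI: \code{roi}, \code{beta_lesion},
#'   \code{beta_exposure}, \code{beta_interaction}, \code{p_interaction},
#'   \code{n_lesioned}, \code{method}, \code{low_support},
#'   \code{significant}, \code{skipped}.
#' @export
map_interactions <- function(data, burden, outcome, exposure = "low_tmt",
                             covariates = covariate_set(FALSE),
                             alpha = 0.05, rois = NULL) {
  stopifnot(inherits(burden, "roi_burden"))
  B <- burden$burden
  if (nrow(B) != nrow(data)) {
    stop("burden matrix rows do not match the analysis data")
  }
  keep <- stats::complete.cases(data[c(exposure, outcome, covariates)])
  df <- data[keep, , drop = FALSE]
  B <- B[keep, , drop = FALSE]
  y <- as.numeric(df[[outcome]])
  x <- as.numeric(df[[exposure]])
  des <- logistic_design(df, c(exposure, covariates))
  exp_term <- grep(paste0("^", exposure), colnames(des$x), value = TRUE)[1]

  if (is.null(rois)) rois <- colnames(B)
  if (!all(rois %in% colnames(B))) {
    stop("unknown ROI: ", paste(setdiff(rois, colnames(B)), collapse = ", "))
  }
  rows <- lapply(rois, function(roi) {
    base <- data.frame(roi = roi, beta_lesion = NA_real_,
                       beta_exposure = NA_real_,
                       beta_interaction = NA_real_,
                       p_interaction = NA_real_,
                       n_lesioned = sum(B[, roi] > 0),
                       method = NA_character_, low_support = FALSE,
                       significant = FALSE, skipped = TRUE,
                       reason = "no lesioned subject",
                       stringsAsFactors = FALSE)
    les <- B[, roi]
    if (all(les == 0)) return(base)
    if (all(les[x == 1] == 0) || all(les[x == 0] == 0)) {
      # all lesioned subjects in one exposure stratum: the product term is
      # aliased with zero or with the lesion column
      base$reason <- "lesioned subjects in one exposure stratum only"
      return(base)
    }
    X <- cbind(des$x, lesion = les, interaction = x * les)
    low_support <- base$n_lesioned < 5
    fit <- tryCatch(
      fit_auto(X, y, strata = x, force = if (low_support) "Firth" else NULL),
      error = function(e) NULL)
    if (is.null(fit)) {
      base$reason <- "model could not be fitted"
      return(base)
    }
    bi <- match(c("lesion", exp_term, "interaction"), fit$terms)
    base$beta_lesion <- fit$beta[bi[1]]
    base$beta_exposure <- fit$beta[bi[2]]
    base$beta_interaction <- fit$beta[bi[3]]
    z <- fit$beta[bi[3]] / fit$se[bi[3]]
    base$p_interaction <- 2 * pnorm(-abs(z))
    base$method <- fit$method
    base$low_support <- low_support
    base$significant <- is.finite(base$p_interaction) &&
      base$p_interaction < alpha
    base$skipped <- FALSE
    base$reason <- ""
    base
  })
  do.call(rbind, rows)
}

#' Simulate a full mapping study (cohort + lesions + planted interaction)
#'
#' Runs \code{\link{simulate_cohort}} and \code{\link{simulate_lesions}},
#' computes ROI burdens on the priority-merged toy atlases, then redraws
#' the 3-month poor-outcome flag from a logistic model that adds the
#' configured per-ROI lesion effects and lesion-by-exposure interaction
#' terms (\code{effect_sizes$roi_lesion_mrs3},
#' \code{effect_sizes$roi_interaction}, named by merged-atlas region), and
#' rebuilds the mRS trajectory to match. With both maps empty this is the
#' plain pipeline under a global null for lesion-location effects.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohort}, \code{nihss}, \code{lesions},
#'   \code{atlas} (merged \code{atlas_set}), \code{burden}.
#' @export
simulate_study <- function(config) {
  sim <- simulate_cohort(config)
  les <- simulate_lesions(sim$cohort, config)
  atlas <- merge_atlases(les$atlases,
                         priority = c("brainstem_toy", "aal_toy", "jhu_toy"),
                         voxel_volume_mm3 = config$lesion_params$voxel_volume_mm3)
  burden <- roi_burden(les$lesions, atlas)
  cohort <- les$cohort
  es <- config$effect_sizes
  pl <- attr(sim$cohort, "planted")

  if (length(es$roi_interaction) || length(es$roi_lesion_mrs3) ||
      es$lesion_total_mrs3 != 0) {
    set.seed(substream_seed(config$seed, 4L))
    cp <- config$covariate_params
    nihss_adm <- tapply(sim$nihss$total, sim$nihss$subject_id,
                        function(t) t[1])[as.character(cohort$subject_id)]
    znihss <- (as.numeric(nihss_adm) - 4.5) / 4
    zage <- (cohort$age - cp$age_mean) / cp$age_sd
    lp <- qlogis(cp$base_rate_mrs3) +
      es$exposure_mrs3_direct * pl$low_tmt +
      es$med_dysphagia_mrs3 * pl$dysphagia +
      es$med_end_mrs3 * pl$end +
      es$med_postdis_mrs3 * pl$postdis_intent +
      0.9 * znihss + 0.35 * zage +
      es$lesion_total_mrs3 * burden$total
    for (nm in names(es$roi_lesion_mrs3)) {
      lp <- lp + es$roi_lesion_mrs3[[nm]] * burden$burden[, nm]
    }
    for (nm in names(es$roi_interaction)) {
      lp <- lp + es$roi_interaction[[nm]] * pl$low_tmt * burden$burden[, nm]
    }
    y3 <- rbinom(nrow(cohort), 1, plogis(lp)) == 1
    dis_total <- tapply(sim$nihss$total, sim$nihss$subject_id,
                        function(t) t[length(t)])[as.character(cohort$subject_id)]
    mrs <- build_mrs_trajectory(
      n = nrow(cohort), dis_total = as.integer(dis_total),
      low_tmt = pl$low_tmt, dysphagia = pl$dysphagia, end_flag = pl$end,
      postdis_intent = pl$postdis_intent,
      chronic_intent = pl$chronic_intent,
      znihss = znihss, zage = zage, es = es, cp = cp,
      followup_loss_rate_1y = config$followup_loss_rate_1y, y3 = y3)
    cohort$mrs_discharge <- mrs$mrs_discharge
    cohort$mrs_3mo <- mrs$mrs_3mo
    cohort$mrs_1y <- mrs$mrs_1y
    pl$mrs3_poor <- y3
    attr(cohort, "planted") <- pl
  }

  list(cohort = cohort, nihss = sim$nihss, lesions = les$lesions,
       atlas = atlas, burden = burden)
}
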