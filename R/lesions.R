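#' @title Toy lesion masks and atlases
#' @description Contiguous random lesion blobs on a small template grid,
#'   plus toy atlases with left/right homologous labels and a
#'   brainstem-like label set, sharing one grid and voxel volume. These
#'   stand in for spatially normalized DWI masks and the AAL / JHU /
#'   brainstem atlas triplet; they are synthetic by construction and make
#'   the ROI-mapping machinery testable end to end.
#' @name toy-lesions
NULL

# fraction-of-axis block as voxel coordinate ranges
.block <- function(dims, xf, yf, zf) {
  rng <- function(f, n) {
    lo <- max(1L, as.integer(ceiling(f[1] * n)))
    hi <- min(n, as.integer(floor(f[2] * n)))
    lo:hi
  }
  list(x = rng(xf, dims[1]), y = rng(yf, dims[2]), z = rng(zf, dims[3]))
}

.paint <- function(arr, blk, value) {
  arr[blk$x, blk$y, blk$z] <- value
  arr
}

#' Toy atlases on the template grid
#'
#' Three overlapping toy atlases: an AAL-like grey-matter atlas (cortex,
#' pallidum, cerebellum; left/right), a JHU-like white-matter atlas
#' (corticospinal and fronto-pontine tract columns; left/right), and a
#' brainstem-like atlas (midbrain, pons, medulla slabs plus left/right
#' middle cerebellar peduncles). Blocks are defined as fractions of the
#' grid so any grid of at least 8 voxels per axis works.
#'
#' @param dims integer length-3 grid dimensions.
#' @return named list of three atlases, each a list with \code{name},
#'   \code{labels} (integer 3D array, 0 = unlabeled) and \code{table}
#'   (data frame: \code{value}, \code{region}, \code{hemisphere}).
#' @export
toy_atlases <- function(dims = c(20L, 20L, 20L)) {
  mk <- function(name, regions) {
    arr <- array(0L, dims)
    tab <- data.frame(value = integer(0), region = character(0),
                      hemisphere = character(0), stringsAsFactors = FALSE)
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      arr <- .paint(arr, .block(dims, r$x, r$y, r$z), i)
      tab <- rbind(tab, data.frame(value = i, region = names(regions)[i],
                                   hemisphere = r$hemi,
                                   stringsAsFactors = FALSE))
    }
    list(name = name, labels = arr, table = tab)
  }
  L <- c(0, 0.5); R <- c(0.5001, 1)
  aal <- mk("aal_toy", list(
    cortex_L    = list(x = L, y = c(0, 1), z = c(0.70, 1), hemi = "L"),
    cortex_R    = list(x = R, y = c(0, 1), z = c(0.70, 1), hemi = "R"),
    pallidum_L  = list(x = c(0.25, 0.45), y = c(0.35, 0.65),
                       z = c(0.40, 0.60), hemi = "L"),
    pallidum_R  = list(x = c(0.55, 0.75), y = c(0.35, 0.65),
                       z = c(0.40, 0.60), hemi = "R"),
    cerebellum_L = list(x = L, y = c(0.5, 1), z = c(0, 0.28), hemi = "L"),
    cerebellum_R = list(x = R, y = c(0.5, 1), z = c(0, 0.28), hemi = "R")
  ))
  jhu <- mk("jhu_toy", list(
    corticospinal_tract_L = list(x = c(0.30, 0.45), y = c(0.45, 0.60),
                                 z = c(0.12, 0.70), hemi = "L"),
    corticospinal_tract_R = list(x = c(0.55, 0.70), y = c(0.45, 0.60),
                                 z = c(0.12, 0.70), hemi = "R"),
    frontopontine_tract_L = list(x = c(0.30, 0.45), y = c(0.22, 0.40),
                                 z = c(0.12, 0.70), hemi = "L"),
    frontopontine_tract_R = list(x = c(0.55, 0.70), y = c(0.22, 0.40),
                                 z = c(0.12, 0.70), hemi = "R")
  ))
  bst <- mk("brainstem_toy", list(
    midbrain = list(x = c(0.40, 0.60), y = c(0.40, 0.60),
                    z = c(0.30, 0.40), hemi = "M"),
    pons     = list(x = c(0.40, 0.60), y = c(0.40, 0.60),
                    z = c(0.18, 0.30), hemi = "M"),
    medulla  = list(x = c(0.40, 0.60), y = c(0.40, 0.60),
                    z = c(0.08, 0.18), hemi = "M"),
    middle_cerebellar_peduncle_L = list(x = c(0.22, 0.40),
                                        y = c(0.40, 0.60),
                                        z = c(0.18, 0.30), hemi = "L"),
    middle_cerebellar_peduncle_R = list(x = c(0.60, 0.78),
                                        y = c(0.40, 0.60),
                                        z = c(0.18, 0.30), hemi = "R")
  ))
  list(brainstem_toy = bst, aal_toy = aal, jhu_toy = jhu)
}

# grow a contiguous blob of `size` voxels from a seed by repeatedly adding
# a random 6-neighbour of the current blob; returns linear voxel indices
grow_blob <- function(dims, size, start, brain = NULL) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nvox <- nx * ny * nz
  in_blob <- logical(nvox)
  blob <- integer(size)
  blob[1] <- start
  in_blob[start] <- TRUE
  neighbours <- function(idx) {
    i0 <- idx - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
    nb <- c(if (x > 0) idx - 1L, if (x < nx - 1) idx + 1L,
            if (y > 0) idx - nx, if (y < ny - 1) idx + nx,
            if (z > 0) idx - nx * ny, if (z < nz - 1) idx + nx * ny)
    nb
  }
  frontier <- neighbours(start)
  if (!is.null(brain)) frontier <- frontier[brain[frontier]]
  k <- 1L
  while (k < size && length(frontier)) {
    pick <- sample.int(length(frontier), 1)
    v <- frontier[pick]
    frontier <- frontier[-pick]
    if (in_blob[v]) next
    k <- k + 1L
    blob[k] <- v
    in_blob[v] <- TRUE
    nb <- neighbours(v)
    nb <- nb[!in_blob[nb]]
    if (!is.null(brain)) nb <- nb[brain[nb]]
    frontier <- c(frontier, nb)
  }
  blob[seq_len(k)]
}

#' Simulate contiguous lesion blobs for a cohort
#'
#' Each subject gets one contiguous blob grown from a uniformly seeded
#' voxel; the blob size is lognormal (configured in
#' \code{lesion_params}). The subject's \code{infarct_volume_pct} is
#' recomputed from the mask as lesioned voxels / brain voxels x 100, and
#' \code{lesion_mask_ref} is filled in.
#'
#' @param cohort cohort data frame from \code{\link{simulate_cohort}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{lesions} (class \code{lesion_set}: \code{masks}
#'   named list of voxel index vectors, \code{dim},
#'   \code{voxel_volume_mm3}, \code{brain} logical vector),
#'   \code{atlases} (from \code{\link{toy_atlases}}), and \code{cohort}
#'   (updated).
#' @export
simulate_lesions <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  lp <- config$lesion_params
  dims <- as.integer(lp$dim)
  nvox <- prod(dims)
  brain <- rep(TRUE, nvox)  # toy template: whole grid is brain
  set.seed(substream_seed(config$seed, 3L))
  n <- nrow(cohort)
  sizes <- pmin(pmax(round(exp(rnorm(n, lp$size_meanlog, lp$size_sdlog))), 1),
                lp$size_max)
  starts <- sample.int(nvox, n, replace = TRUE)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    masks[[i]] <- sort(grow_blob(dims, sizes[i], starts[i], brain))
  }
  names(masks) <- sprintf("mask_%05d", cohort$subject_id)
  cohort$infarct_volume_pct <- 100 * lengths(masks) / sum(brain)
  cohort$lesion_mask_ref <- names(masks)
  lesions <- structure(list(masks = masks, dim = dims,
                            voxel_volume_mm3 = lp$voxel_volume_mm3,
                            brain = brain),
                       class = "lesion_set")
  list(lesions = lesions, atlases = toy_atlases(dims), cohort = cohort)
}

#' Infarct volume as percentage of total brain volume
#'
#' @param mask integer voxel indices (or logical array) of the lesion.
#' @param brain logical vector/array marking brain voxels.
#' @return percentage in [0, 100].
#' @export
infarct_volume_pct <- function(mask, brain) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) && any(!brain[mask])) {
    warning("lesion voxels outside the brain mask are not counted")
    mask <- mask[brain[mask]]
  }
  100 * length(mask) / sum(brain)
}

#' Write lesion masks and a merged atlas as NIfTI
#'
#' Masks and atlas volumes share the grid and an identity-scaled affine
#' (voxel edge from the voxel volume), matching the common-template
#' contract for real data.
#'
#' @param lesions a \code{lesion_set}.
#' @param atlas_set an \code{atlas_set} from \code{\link{merge_atlases}}.
#' @param dir output directory (created).
#' @return invisibly, the written file paths.
#' @export
write_mapping_nifti <- function(lesions, atlas_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge <- lesions$voxel_volume_mm3^(1 / 3)
  paths <- character(0)
  for (nm in names(lesions$masks)) {
    arr <- array(0L, lesions$dim)
    arr[lesions$masks[[nm]]] <- 1L
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(edge, 3)), p)
    paths <- c(paths, p)
  }
  pa <- file.path(dir, "atlas_merged.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas_set$merged,
                                     pixdim = rep(edge, 3)), pa)
  pt <- file.path(dir, "atlas_labels.csv")
  utils::write.csv(atlas_set$table, pt, row.names = FALSE)
  invisible(c(paths, pa, pt))
}
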