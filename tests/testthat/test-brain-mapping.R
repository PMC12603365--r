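toy2 <- function(dims, blocks) {
  # tiny helper to build an atlas from explicit voxel index sets
  arr <- array(0L, dims)
  tab <- data.frame(value = integer(0), region = character(0),
                    hemisphere = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(blocks)) {
    arr[blocks[[i]]] <- i
    tab <- rbind(tab, data.frame(value = i, region = names(blocks)[i],
                                 hemisphere = "M",
                                 stringsAsFactors = FALSE))
  }
  list(name = "x", labels = arr, table = tab)
}

test_that("atlas merge resolves overlaps by priority and keeps provenance", {
  dims <- c(8L, 8L, 8L)
  a1 <- toy2(dims, list(r1 = 1:40))
  a2 <- toy2(dims, list(r2 = 30:80))
  a3 <- toy2(dims, list(r3 = 70:120))
  a1$name <- "one"; a2$name <- "two"; a3$name <- "three"
  ats <- list(one = a1, two = a2, three = a3)
  m <- merge_atlases(ats, priority = c("one", "two", "three"))

  # voxel claimed by atlases two and three only -> atlas-two label
  v_23 <- 75
  lab <- m$merged[v_23]
  expect_equal(m$table$atlas[m$table$value == lab], "two")
  # voxel claimed by all three -> highest priority
  lab1 <- m$merged[35]
  expect_equal(m$table$atlas[m$table$value == lab1], "one")
  # unclaimed stays 0
  expect_equal(m$merged[500], 0L)

  # disjoint atlases merge to the union regardless of priority
  b1 <- toy2(dims, list(p = 1:20)); b1$name <- "b1"
  b2 <- toy2(dims, list(q = 100:130)); b2$name <- "b2"
  mu <- merge_atlases(list(b1 = b1, b2 = b2), c("b1", "b2"))
  expect_equal(sum(mu$merged > 0), 20 + 31)

  expect_error(merge_atlases(ats, c("one", "one", "two")), "duplicate")
  bad <- a1; bad$labels <- array(0L, c(9, 8, 8))
  expect_error(merge_atlases(list(one = bad, two = a2), c("one", "two")),
               "grid")
})

test_that("priority merge equals a voxel-by-voxel brute-force loop on random atlases", {
  set.seed(21)
  dims <- c(16L, 16L, 16L)
  nvox <- prod(dims)
  mk <- function(nm, k) {
    blocks <- lapply(seq_len(k), function(i) sample.int(nvox, 300))
    names(blocks) <- paste0(nm, "_", seq_len(k))
    a <- toy2(dims, blocks)
    a$name <- nm
    a
  }
  ats <- list(A = mk("A", 3), B = mk("B", 3), C = mk("C", 2))
  pri <- c("B", "A", "C")
  m <- merge_atlases(ats, priority = pri)

  prov <- m$table
  for (v in sample.int(nvox, 600)) {
    want_atlas <- NA_character_
    want_region <- NA_character_
    for (nm in pri) {
      lv <- ats[[nm]]$labels[v]
      if (lv > 0) {
        want_atlas <- nm
        want_region <- ats[[nm]]$table$region[ats[[nm]]$table$value == lv]
        break
      }
    }
    got <- m$merged[v]
    if (is.na(want_atlas)) {
      expect_equal(got, 0L)
    } else {
      expect_equal(prov$atlas[prov$value == got], want_atlas)
      expect_equal(prov$region[prov$value == got], want_region)
    }
  }

  # permuting the priority changes only multiply-claimed voxels
  m2 <- merge_atlases(ats, priority = c("C", "B", "A"))
  claimed_by <- (ats$A$labels > 0) + (ats$B$labels > 0) + (ats$C$labels > 0)
  reg_of <- function(m, v) {
    if (m$merged[v] == 0) "" else m$table$region[m$table$value == m$merged[v]]
  }
  single <- which(claimed_by == 1)
  for (v in sample(single, 100)) {
    expect_equal(reg_of(m, v), reg_of(m2, v))
  }
})

test_that("ROI burden matches direct ratios and is bounded by the subject total", {
  dims <- c(20L, 20L, 20L)
  ats <- toy_atlases(dims)
  atlas <- merge_atlases(ats, c("brainstem_toy", "aal_toy", "jhu_toy"))
  roi <- "pallidum_L"
  roi_val <- atlas$table$value[atlas$table$region == roi]
  roi_vox <- which(atlas$merged == roi_val)

  lesions <- structure(list(
    masks = list(empty = integer(0), exact = roi_vox,
                 mixed = c(roi_vox[1:5], which(atlas$merged == 0)[1:10])),
    dim = dims, voxel_volume_mm3 = 1, brain = rep(TRUE, prod(dims))),
    class = "lesion_set")
  bb <- roi_burden(lesions, atlas)
  expect_equal(unname(bb$burden["empty", ]),
               rep(0, ncol(bb$burden)))
  expect_equal(unname(bb$burden["exact", roi]),
               100 * length(roi_vox) / 8000)
  expect_equal(unname(bb$total[["exact"]]), 100 * length(roi_vox) / 8000)
  # unlabeled voxels contribute to the total but no ROI column
  expect_lt(sum(bb$burden["mixed", ]), bb$total[["mixed"]])
  expect_equal(unname(rowSums(bb$burden) <= bb$total + 1e-12),
               rep(TRUE, 3))

  # burden invariant to ROI integer relabeling
  atlas2 <- atlas
  perm <- sample(seq_len(nrow(atlas2$table)))
  old <- atlas2$table$value
  new <- old[perm]
  relab <- atlas2$merged
  for (i in seq_along(old)) relab[atlas$merged == old[i]] <- new[i]
  atlas2$merged <- relab
  atlas2$table$value <- new
  b2 <- roi_burden(lesions, atlas2)
  expect_equal(b2$burden[, colnames(bb$burden)], bb$burden)

  bad <- lesions
  bad$masks$exact <- c(bad$masks$exact, prod(dims) + 5L)
  expect_error(roi_burden(bad, atlas), "off-grid")
})

test_that("symmetric pooling adds left and right burdens exactly", {
  cfg <- sim_config(60, seed = 3)
  st <- simulate_study(cfg)
  pooled <- pool_symmetric(st$burden)
  pairing <- symmetric_pairing(st$atlas)
  for (i in seq_len(nrow(pairing))) {
    l <- st$burden$burden[, pairing$left[i]]
    r <- if (pairing$left[i] == pairing$right[i]) 0 else
      st$burden$burden[, pairing$right[i]]
    expect_equal(unname(pooled$burden[, pairing$pooled[i]]),
                 unname(l + r))
  }
  # midline brainstem labels pool to themselves
  expect_true(all(c("midbrain", "pons", "medulla") %in%
                    colnames(pooled$burden)))

  bad_pairs <- data.frame(left = c("cortex_L", "cortex_L"),
                          right = c("cortex_R", "cerebellum_R"),
                          pooled = c("cortex", "weird"))
  expect_error(pool_symmetric(st$burden, bad_pairs), "two pairs")
})

test_that("interaction mapping skips degenerate ROIs and reports the fitted terms", {
  cfg <- sim_config(400, seed = 17)
  st <- simulate_study(cfg)
  dat <- analysis_table(st$cohort, st$nihss)
  burden <- st$burden
  burden$burden <- cbind(burden$burden, all_zero = 0)
  res <- map_interactions(dat, burden, "mrs3_ge3")
  expect_true(res$skipped[res$roi == "all_zero"])
  fitted <- res[!res$skipped, ]
  expect_true(all(is.finite(fitted$p_interaction)))
  expect_true(all(fitted$method %in% c("ML", "Firth")))
  expect_equal(fitted$significant, fitted$p_interaction < 0.05)
  expect_true(all(res$n_lesioned[!res$skipped] > 0))
})

test_that("permuting exposure labels destroys a planted interaction signal", {
  cfg <- sim_config(2000, seed = 29,
                    effect_sizes = list(roi_interaction = c(cortex_L = 7)))
  st <- simulate_study(cfg)
  dat <- analysis_table(st$cohort, st$nihss)
  obs <- map_interactions(dat, st$burden, "mrs3_ge3")
  p_obs <- obs$p_interaction[obs$roi == "cortex_L"]

  set.seed(31)
  p_perm <- replicate(15, {
    dp <- dat
    dp$low_tmt <- sample(dp$low_tmt)
    mp <- map_interactions(dp, st$burden, "mrs3_ge3",
                           covariates = c("age", "sex", "nihss_admission"),
                           rois = "cortex_L")
    mp$p_interaction[mp$roi == "cortex_L"]
  })
  expect_lt(p_obs, 0.05)
  expect_gt(median(p_perm), 0.15)
  expect_gt(mean(p_perm > p_obs), 0.8)
})
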