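test_that("sphere offsets match brute-force lattice enumeration for radii 1..5", {
  for (r in 1:5) {
    count <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
      if (dx^2 + dy^2 + dz^2 < r^2) count <- count + 1
    expect_equal(nrow(sphere_offsets(r)), count, label = paste("radius", r))
  }
  expect_equal(nrow(sphere_offsets(1)), 1)   # center only
  expect_equal(nrow(sphere_offsets(3)), 93)
})

test_that("coverage filtering is strict at the 50% boundary", {
  off <- sphere_offsets(3)
  ## all-true mask: interior centers all kept
  mask <- array(TRUE, c(9, 9, 9))
  vc <- valid_centers(mask, off)
  expect_true(all(vc$coverage[4:6, 4:6, 4:6] == 1))
  expect_true(((5 - 1) * 81 + (5 - 1) * 9 + 5) %in% vc$index)  # center kept
  ## hand-built 7^3 mask: compare against a per-center manual count
  set.seed(50)
  mask2 <- array(runif(343) < 0.7, c(7, 7, 7))
  vc2 <- valid_centers(mask2, off)
  manual <- integer(0)
  for (x in 1:7) for (y in 1:7) for (z in 1:7) {
    if (!mask2[x, y, z]) next
    inside <- 0
    for (k in seq_len(nrow(off))) {
      p <- c(x, y, z) + off[k, ]
      if (all(p >= 1 & p <= 7) && mask2[p[1], p[2], p[3]]) inside <- inside + 1
    }
    if (inside / nrow(off) > 0.5) manual <- c(manual, (z - 1) * 49 + (y - 1) * 7 + x)
  }
  expect_equal(sort(vc2$index), sort(manual))
  ## a center with exactly 46 of 93 inside (49.5%) is discarded
  expect_false(46 / 93 > 0.5)
})

test_that("searchlight maps light up planted regions and only there", {
  labs <- paste0("s", 1:5)
  mods <- orthogonal_model_rdms(labs, seed = 3)
  dims <- c(12, 12, 12)
  ra <- array(FALSE, dims); ra[3:7, 3:7, 3:7] <- TRUE
  rb <- array(FALSE, dims); rb[7:11, 8:12, 8:12] <- TRUE
  rb[ra] <- FALSE
  bv <- simulate_beta_volumes(mods, dims, region_a = ra, region_b = rb,
                              n_runs = 4, snr = 4, seed = 11)
  maps <- searchlight_rsa(bv, mods)
  core_a <- array(FALSE, dims); core_a[4:6, 4:6, 4:6] <- TRUE
  core_b <- array(FALSE, dims); core_b[8:10, 9:11, 9:11] <- TRUE
  expect_gt(mean(maps$A[core_a], na.rm = TRUE), 0.8)
  expect_gt(mean(maps$B[core_b], na.rm = TRUE), 0.8)
  ## spheres whose radius-3 reach misses both regions see pure noise: the
  ## map there is centered on 0 (single-sphere correlations over 10 entries
  ## fluctuate, but carry no systematic similarity)
  co <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  reach <- function(region) {
    rc <- which(region, arr.ind = TRUE)
    apply(co, 1, function(p) min(sqrt(colSums((t(rc) - as.numeric(p))^2)))) < 3
  }
  halo <- array(reach(ra) | reach(rb), dims)
  outside <- !halo & !is.na(maps$A)
  expect_gt(sum(outside), 50)
  ## with only 10 RDM entries per sphere, noise correlations carry a small
  ## model-dependent offset; the planted regions must stand far above it
  expect_lt(abs(mean(maps$A[outside])), 0.2)
  expect_lt(abs(mean(maps$B[outside])), 0.2)
  expect_gt(mean(maps$A[core_a], na.rm = TRUE) - mean(maps$A[outside]), 0.6)
  expect_gt(mean(maps$B[core_b], na.rm = TRUE) - mean(maps$B[outside]), 0.6)
  ## permuting condition labels of the betas destroys the map
  bp <- bv
  perm <- c(3, 5, 1, 2, 4)
  bp$data <- bv$data[, , , perm, ]
  maps_p <- searchlight_rsa(bp, mods)
  expect_lt(mean(maps_p$A[core_a], na.rm = TRUE), 0.2)
  ## swapping the planted regions swaps the model maps
  bv2 <- simulate_beta_volumes(mods, dims, region_a = rb, region_b = ra,
                               n_runs = 4, snr = 4, seed = 11)
  maps2 <- searchlight_rsa(bv2, mods)
  expect_gt(mean(maps2$B[core_a], na.rm = TRUE), 0.8)
  expect_gt(mean(maps2$A[core_b], na.rm = TRUE), 0.8)
})

test_that("gaussian smoothing has the right width and respects masks", {
  dims <- c(21, 21, 21)
  ## delta input: measured FWHM within half a voxel of 8 mm (4 voxels at 2 mm)
  m <- array(0, dims); m[11, 11, 11] <- 1
  sm <- smooth_volume(m, fwhm_mm = 8, voxel_size = 2)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  above <- which(prof >= half)
  ## linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_vox <- f_hi - f_lo
  expect_lt(abs(fwhm_vox * 2 - 8), 1)   # within half a voxel (1 mm)
  ## identity at fwhm 0, constants unchanged under mask-aware normalization
  expect_identical(smooth_volume(m, 0, 2), m)
  cst <- array(2.5, dims)
  mask <- array(FALSE, dims); mask[5:17, 5:17, 5:17] <- TRUE
  cst[!mask] <- NA
  smc <- smooth_volume(cst, 8, 2, mask = mask)
  expect_equal(smc[mask], rep(2.5, sum(mask)), tolerance = 1e-9)
  expect_true(all(is.na(smc[!mask])))
})

test_that("subject-specific ROI selection never double dips", {
  set.seed(51)
  n_vox <- 200
  roi <- rep(TRUE, n_vox)
  ## planted activated subregion in the first 20 voxels
  C <- matrix(rnorm(6 * n_vox, 0, 0.5), 6)
  C[, 1:20] <- C[, 1:20] + 2
  r <- subject_specific_roi(C, roi, 0.10)
  expect_equal(r$n_selected, 20)
  expect_gt(r$estimate, mean(C))   # beats the whole-ROI mean
  ## identical responses across runs: estimate equals the top-decile mean
  C2 <- matrix(rep(seq_len(n_vox), each = 4), 4, byrow = FALSE)
  r2 <- subject_specific_roi(C2, roi, 0.10)
  expect_equal(r2$estimate, mean(181:200))
  ## selection and estimation runs are disjoint in every fold: selecting on
  ## a run whose own values are inflated must not inflate the estimate
  C3 <- matrix(rnorm(4 * n_vox), 4)
  C3[2, ] <- C3[2, ] + 100
  r3 <- subject_specific_roi(C3, roi, 0.10)
  expect_lt(r3$per_fold[2], 50)   # fold 2 averages only the other runs
  expect_warning(subject_specific_roi(C3[, 1:5], rep(TRUE, 5)), "10 voxels")
})
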