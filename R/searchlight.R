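## Volumetric searchlight RSA -------------------------------------------------
##
## A sphere of voxels (integer offsets with Euclidean norm strictly below the
## radius; radius 3 gives 93 voxels) is swept across the brain. At each
## center with more than 50% of its sphere inside the brain mask, a
## crossnobis RDM is computed from the per-run condition betas of the sphere
## voxels and compared to each model RDM with a whitened correlation; the
## similarity is assigned to the center voxel.

#' Integer voxel offsets of a searchlight sphere
#'
#' All offsets with Euclidean norm strictly less than `radius` (center
#' included). Strict inequality at radius 3 yields 93 voxels.
#'
#' @param radius_voxels sphere radius in voxel units (default 3).
#' @return integer matrix `k x 3`.
#' @export
sphere_offsets <- function(radius_voxels = 3) {
  stopifnot(radius_voxels > 0)
  r <- ceiling(radius_voxels)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) < radius_voxels^2, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Searchlight centers with sufficient brain coverage
#'
#' A center is kept iff strictly more than `min_coverage` of its sphere
#' voxels lie inside the mask (a sphere with exactly half its voxels outside
#' is discarded).
#'
#' @param mask logical 3D array.
#' @param offsets offset matrix from [sphere_offsets()].
#' @param min_coverage coverage fraction (default 0.5).
#' @return list with `index` (linear indices of valid centers), `coverage`
#'   (3D array of in-mask sphere fractions).
#' @export
valid_centers <- function(mask, offsets, min_coverage = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)
  cov <- array(0, dims)
  m <- array(as.numeric(mask), dims)
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    src_x <- max(1, 1 + o[1]):min(dims[1], dims[1] + o[1])
    src_y <- max(1, 1 + o[2]):min(dims[2], dims[2] + o[2])
    src_z <- max(1, 1 + o[3]):min(dims[3], dims[3] + o[3])
    dst_x <- src_x - o[1]; dst_y <- src_y - o[2]; dst_z <- src_z - o[3]
    cov[dst_x, dst_y, dst_z] <- cov[dst_x, dst_y, dst_z] + m[src_x, src_y, src_z]
  }
  cov <- cov / nrow(offsets)
  keep <- mask & cov > min_coverage
  list(index = which(keep), coverage = cov)
}

#' Per-run condition beta volumes
#'
#' @param data numeric 5D array `x, y, z, condition, run`.
#' @param mask logical 3D brain mask.
#' @param labels condition labels.
#' @param voxel_size voxel edge in mm (default 2, isotropic).
#' @return object of class `beta_volume`.
#' @export
beta_volumes <- function(data, mask, labels = NULL, voxel_size = 2) {
  stopifnot(is.array(data), length(dim(data)) == 5)
  d <- dim(data)
  stopifnot(all(dim(mask) == d[1:3]))
  if (d[5] < 2) stop("need at least 2 runs for cross-validated distances")
  if (is.null(labels)) labels <- dimnames(data)[[4]]
  if (is.null(labels)) labels <- paste0("c", seq_len(d[4]))
  structure(list(data = data, mask = mask, labels = labels,
                 voxel_size = voxel_size), class = "beta_volume")
}

#' Searchlight crossnobis RSA against model RDMs
#'
#' @param betas a [beta_volumes] object.
#' @param models named list of model [rdm]s over the beta condition labels.
#' @param radius_voxels sphere radius (default 3).
#' @param min_coverage minimum in-mask sphere fraction (default 0.5).
#' @param scheme crossnobis fold scheme (default all run pairs).
#' @return named list of 3D similarity maps (one per model), `NA` outside
#'   the valid centers; attribute `"n_centers"` records the center count.
#' @export
searchlight_rsa <- function(betas, models, radius_voxels = 3,
                            min_coverage = 0.5,
                            scheme = c("all-pairs", "loo")) {
  stopifnot(inherits(betas, "beta_volume"))
  scheme <- match.arg(scheme)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  models <- lapply(models, function(m) {
    if (!identical(m$labels, betas$labels)) subset_rdm(m, betas$labels) else m
  })
  dims <- dim(betas$mask)
  d <- dim(betas$data)
  n_cond <- d[4]; n_run <- d[5]
  offsets <- sphere_offsets(radius_voxels)
  vc <- valid_centers(betas$mask, offsets, min_coverage)
  mask_idx <- which(betas$mask)
  ## flat in-mask voxel x (cond, run) matrix for fast sphere extraction
  flat <- matrix(betas$data, prod(dims), n_cond * n_run)[mask_idx, , drop = FALSE]
  row_of <- integer(prod(dims)); row_of[mask_idx] <- seq_along(mask_idx)
  centers <- arrayInd(vc$index, dims)
  maps <- lapply(models, function(m) array(NA_real_, dims))
  mvals <- lapply(models, `[[`, "values")
  nxyz <- dims
  for (ci in seq_len(nrow(centers))) {
    pos <- sweep(offsets, 2, centers[ci, ], `+`)
    ok <- pos[, 1] >= 1 & pos[, 1] <= nxyz[1] &
          pos[, 2] >= 1 & pos[, 2] <= nxyz[2] &
          pos[, 3] >= 1 & pos[, 3] <= nxyz[3]
    lin <- (pos[ok, 3] - 1) * nxyz[1] * nxyz[2] + (pos[ok, 2] - 1) * nxyz[1] + pos[ok, 1]
    rows <- row_of[lin]
    rows <- rows[rows > 0]
    if (!length(rows)) next
    block <- flat[rows, , drop = FALSE]           # voxels x (cond*run)
    folds <- lapply(seq_len(n_run), function(r)
      t(block[, (r - 1) * n_cond + seq_len(n_cond), drop = FALSE]))
    vals <- .crossnobis_core(folds, scheme = scheme)
    sdv <- stats::sd(vals)
    for (mi in seq_along(models)) {
      maps[[mi]][vc$index[ci]] <- if (sdv == 0) NA_real_ else
        stats::cor(vals, mvals[[mi]])
    }
  }
  structure(maps, n_centers = nrow(centers))
}

#' Gaussian smoothing of a statistic volume
#'
#' Mask-aware separable Gaussian smoothing: missing values and out-of-mask
#' voxels are excluded from the kernels and the result is renormalized, so a
#' constant map stays constant.
#'
#' @param map 3D array (NA = missing).
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size voxel edge in mm.
#' @param mask optional logical 3D array.
#' @return smoothed 3D array (NA where no data contributed).
#' @export
smooth_volume <- function(map, fwhm_mm = 8, voxel_size = 2, mask = NULL) {
  stopifnot(is.array(map), length(dim(map)) == 3)
  if (fwhm_mm <= 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  half <- max(1, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  w <- is.finite(map)
  if (!is.null(mask)) w <- w & mask
  num <- map; num[!w] <- 0
  den <- array(as.numeric(w), dim(map))
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1])
    out <- matrix(0, dp[1], ncol(m))
    for (k in seq_along(kern)) {
      off <- k - half - 1
      src <- max(1, 1 + off):min(dp[1], dp[1] + off)
      dst <- src - off
      out[dst, ] <- out[dst, ] + kern[k] * m[src, ]
    }
    dim(out) <- dp
    aperm(out, order(perm))
  }
  for (ax in 1:3) { num <- conv_axis(num, ax); den <- conv_axis(den, ax) }
  res <- num / den
  res[den <= .Machine$double.eps] <- NA_real_
  if (!is.null(mask)) res[!mask] <- NA_real_
  res
}

#' Cross-validated subject-specific ROI response
#'
#' For each selection run, the top `top_fraction` of in-ROI voxels by that
#' run's contrast are selected and the mean response of the *other* runs
#' over those voxels is collected (no double-dipping); the fold estimates
#' are averaged.
#'
#' @param contrast list of 3D arrays (or matrix `runs x voxels`), one
#'   selection contrast per run.
#' @param roi_mask logical 3D array (or logical vector).
#' @param top_fraction fraction of most responsive voxels (default 0.10).
#' @param responses optional response maps (same shape as `contrast`);
#'   defaults to `contrast`.
#' @return list with `estimate` (mean over folds), `per_fold`, and
#'   `n_selected`.
#' @export
subject_specific_roi <- function(contrast, roi_mask, top_fraction = 0.10,
                                 responses = contrast) {
  tomat <- function(x) if (is.list(x))
    t(vapply(x, as.numeric, numeric(length(x[[1]])))) else x
  C <- tomat(contrast); Rsp <- tomat(responses)
  roi <- which(as.logical(roi_mask))
  n_run <- nrow(C)
  if (n_run < 2) stop("need at least 2 runs")
  n_sel <- max(1, floor(length(roi) * top_fraction))
  if (length(roi) < 10)
    warning("ROI smaller than 10 voxels; top-fraction selection is degenerate")
  per <- vapply(seq_len(n_run), function(r) {
    sel <- roi[order(C[r, roi], decreasing = TRUE)[seq_len(n_sel)]]
    mean(Rsp[-r, sel, drop = FALSE])
  }, numeric(1))
  list(estimate = mean(per), per_fold = per, n_selected = n_sel)
}
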