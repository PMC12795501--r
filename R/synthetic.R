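## Synthetic data with planted representational structure ---------------------
##
## Generators for every input the pipeline consumes: visual-search trial
## tables whose pooled statistics encode a ground-truth dissimilarity
## structure; oddball miniblock designs (30 items, 4 oddballs, none in the
## first 6 positions, never two in a row); MEG-like epoch arrays in which the
## condition-pattern geometry follows one model RDM in an early time window
## and another in a late window, and oddball responses grow and accelerate
## with geometric regularity; and fMRI-like per-run beta volumes with two
## planted regions expressing the two model geometries.

#' Oddball miniblock design
#'
#' @param shape shape label of the block.
#' @param n_items items per block (default 30).
#' @param n_oddballs number of oddballs (default 4); oddballs occupy
#'   positions `>= min_position` and are never adjacent. Positions are
#'   uniform over the valid configuration set (rejection sampling).
#' @param min_position first position an oddball may occupy (default 7).
#' @param scale_set,rotation_set per-item transform values, sampled with
#'   replacement (defaults: the lab six-value sets).
#' @param block index of the block (metadata).
#' @param seed integer seed.
#' @return `design_block`: list with `shape`, `block`, and `items`
#'   (data.frame: position, scale, rotation, is_oddball, direction).
#' @export
make_miniblock_design <- function(shape, n_items = 30, n_oddballs = 4,
                                  min_position = 7,
                                  scale_set = transform_sets("lab")$scales,
                                  rotation_set = transform_sets("lab")$rotations,
                                  block = 1L, seed = NULL) {
  n_slots <- n_items - min_position + 1
  if (n_oddballs > 0 && (n_slots < 2 * n_oddballs - 1))
    stop("oddball constraints unsatisfiable for this n_items/min_position")
  with_seed(seed, {
    pos <- integer(0)
    if (n_oddballs > 0) {
      repeat {
        pos <- sort(sample(min_position:n_items, n_oddballs))
        if (n_oddballs == 1 || all(diff(pos) > 1)) break
      }
    }
    items <- data.frame(
      position = seq_len(n_items),
      scale = sample(scale_set, n_items, replace = TRUE),
      rotation = sample(rotation_set, n_items, replace = TRUE),
      is_oddball = seq_len(n_items) %in% pos,
      direction = NA_integer_)
    items$direction[items$is_oddball] <- sample(1:4, n_oddballs, replace = TRUE)
    structure(list(shape = shape, block = as.integer(block), items = items),
              class = "design_block")
  })
}

#' Validate the three miniblock constraints
#' @param design a `design_block`.
#' @param n_oddballs,min_position expected design parameters.
#' @return TRUE, or an error describing the violated constraint.
#' @export
check_design_block <- function(design, n_oddballs = 4, min_position = 7) {
  pos <- design$items$position[design$items$is_oddball]
  if (length(pos) != n_oddballs) stop("wrong oddball count")
  if (any(pos < min_position)) stop("oddball in the initial positions")
  if (length(pos) > 1 && any(diff(sort(pos)) == 1)) stop("adjacent oddballs")
  TRUE
}

#' Intruder display layout (six shapes on two half circles)
#'
#' Three shapes on the left and three on the right half of a circle of
#' radius 120 px (angles -90, 0, 90 degrees on each half), shifted 100 px
#' outward; one position holds the intruder. Scales and rotations are drawn
#' without replacement from the six-value sets, so no two shapes in a
#' display share a transform.
#'
#' @param reference,intruder distinct shape labels.
#' @param prev_intruder_position optional previous intruder position (1..6),
#'   never repeated on the next display.
#' @param seed integer seed.
#' @return data.frame: position (1..6), x, y, shape, is_intruder, scale,
#'   rotation.
#' @export
make_intruder_display <- function(reference, intruder,
                                  prev_intruder_position = NULL, seed = NULL) {
  if (identical(reference, intruder)) stop("reference must differ from intruder")
  ang <- c(-90, 0, 90) * pi / 180
  right <- cbind(120 * cos(ang) + 100, 120 * sin(ang))
  left <- cbind(-120 * cos(ang) - 100, 120 * sin(ang))
  xy <- rbind(left, right)
  with_seed(seed, {
    cand <- setdiff(1:6, prev_intruder_position)
    ipos <- cand[sample.int(length(cand), 1)]
    tr <- sample_transforms(6, transform_sets("lab")$scales,
                            transform_sets("lab")$rotations)
    data.frame(position = 1:6, x = xy[, 1], y = xy[, 2],
               shape = ifelse(1:6 == ipos, intruder, reference),
               is_intruder = 1:6 == ipos,
               scale = tr$scale, rotation = tr$rotation)
  })
}

#' Simulate visual-search trials from a ground-truth RDM
#'
#' Each participant contributes one trial per ordered pair of distinct
#' shapes. Accuracy increases and response time decreases with the
#' ground-truth dissimilarity `d` (standardized across pairs):
#' `P(correct) = plogis(acc_slope * d + acc_intercept)` and
#' `RT = exp(log_rt_mu - rt_slope * d + noise)`, noise ~ N(0, rt_sigma).
#'
#' @param ground_truth an [rdm] encoding the true dissimilarity structure.
#' @param n_participants number of simulated participants (default 330).
#' @param params list: acc_slope (1.5), acc_intercept (1.5), log_rt_mu
#'   (log 1500 ms), rt_slope (0.25), rt_sigma (0.3).
#' @param seed integer seed.
#' @return a `trial_table` with `n_participants * n * (n-1)` rows.
#' @export
simulate_behavior <- function(ground_truth, n_participants = 330,
                              params = list(), seed = 1) {
  stopifnot(inherits(ground_truth, "rdm"))
  p <- utils::modifyList(list(acc_slope = 1.5, acc_intercept = 1.5,
                              log_rt_mu = log(1500), rt_slope = 0.25,
                              rt_sigma = 0.3), params)
  labels <- ground_truth$labels
  d <- ground_truth$values
  d <- (d - mean(d)) / stats::sd(d)
  m <- as.matrix(rdm(d, labels))
  n <- length(labels)
  op <- expand.grid(i = seq_len(n), j = seq_len(n))
  op <- op[op$i != op$j, ]
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_participants), function(pid) {
      dv <- m[cbind(op$i, op$j)]
      pc <- stats::plogis(p$acc_slope * dv + p$acc_intercept)
      data.frame(participant = pid,
                 reference = labels[op$i], intruder = labels[op$j],
                 correct = stats::runif(nrow(op)) < pc,
                 rt = exp(p$log_rt_mu - p$rt_slope * dv +
                          stats::rnorm(nrow(op), 0, p$rt_sigma)))
    }))
    validate_trials(rows)
  })
}

#' Embed an RDM as condition patterns in channel space
#'
#' Classical-scaling (Torgerson) embedding of the square-rooted
#' dissimilarities, so that squared Euclidean distances between the returned
#' condition patterns reproduce the RDM values (exactly for
#' Euclidean-realizable RDMs such as Hamming feature distances). The
#' embedding is padded with zero dimensions and rotated into channel space
#' by a seeded random orthonormal map; patterns are centered and scaled to
#' unit root-mean-square entry.
#'
#' @param x an [rdm] with non-negative values.
#' @param n_channels number of channels (must be >= conditions - 1).
#' @param seed integer seed for the rotation.
#' @return matrix `conditions x n_channels` with attribute `"scale"` (the
#'   factor such that squared pattern distances = scale * RDM values).
#' @export
embed_rdm_patterns <- function(x, n_channels, seed = 1) {
  stopifnot(inherits(x, "rdm"))
  if (any(x$values < 0)) stop("cannot embed an RDM with negative values")
  n <- n_conditions(x)
  if (n_channels < n - 1) stop("need at least conditions-1 channels")
  D <- sqrt(as.matrix(x))
  cmd <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  pts <- cmd$points
  if (ncol(pts) < n - 1)
    pts <- cbind(pts, matrix(0, n, n - 1 - ncol(pts)))
  Q <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(n_channels^2), n_channels))))
  out <- cbind(pts, matrix(0, n, n_channels - ncol(pts))) %*% Q
  ## normalize AFTER rotation so the per-channel RMS amplitude is 1
  ## regardless of the channel count
  rms <- sqrt(mean(out^2))
  out <- out / rms
  rownames(out) <- x$labels
  attr(out, "scale") <- 1 / rms^2
  out
}

#' Random symmetric positive-definite channel covariance
#'
#' Eigenvalues are drawn log-uniformly with condition number at most
#' `max_condition`, eigenvectors from a random orthonormal basis; the matrix
#' is scaled to unit mean variance.
#'
#' @param p dimension.
#' @param max_condition maximum condition number (default 10).
#' @param seed integer seed.
#' @return p x p SPD matrix.
#' @export
random_spd <- function(p, max_condition = 10, seed = 1) {
  with_seed(seed, {
    ev <- exp(stats::runif(p, 0, log(max_condition)))
    Q <- qr.Q(qr(matrix(stats::rnorm(p^2), p)))
    S <- Q %*% (ev * t(Q))
    S / mean(diag(S))
  })
}

#' A pair of effectively orthogonal model RDMs
#'
#' Two Euclidean-realizable RDMs over the same labels whose entry vectors
#' are nearly uncorrelated, emulating the situation where two encoding
#' models (e.g. a low-level visual model and a symbolic feature model) make
#' independent predictions. Built as squared distances of two independent
#' random Gaussian configurations, retrying until the entry vectors are
#' nearly uncorrelated (|r| < 0.05 or the best of 50 draws).
#'
#' @param labels condition labels.
#' @param seed integer seed.
#' @param dim latent configuration dimension (default 3).
#' @return named list of two [rdm]s `A` and `B` (their entry correlation is
#'   reported in attribute `"cor"`).
#' @export
orthogonal_model_rdms <- function(labels, seed = 1, dim = 3) {
  n <- length(labels)
  with_seed(seed, {
    best <- NULL
    for (i in 1:50) {
      xa <- matrix(stats::rnorm(n * dim), n)
      xb <- matrix(stats::rnorm(n * dim), n)
      va <- as.numeric(stats::dist(xa))^2
      vb <- as.numeric(stats::dist(xb))^2
      r <- abs(stats::cor(va, vb))
      if (is.null(best) || r < best$r) best <- list(va = va, vb = vb, r = r)
      if (r < 0.05) break
    }
    A <- rdm(best$va, labels, metric = "synthetic-model")
    B <- rdm(best$vb, labels, metric = "synthetic-model")
    out <- list(A = A, B = B)
    attr(out, "cor") <- stats::cor(A$values, B$values)
    out
  })
}

#' Simulation specification for MEG-like epochs
#'
#' @param model_rdms named list of two model [rdm]s (geometry `A` expressed
#'   in the early window, `B` in the late window); labels define the shapes.
#' @param windows named list of `c(start, end)` in seconds (defaults:
#'   A = 60-320 ms, B = 128-400 ms).
#' @param regularity per-shape predictor driving the oddball effect
#'   (defaults to the feature counts of the reference shapes when labels
#'   match the 11 families, else 0).
#' @param n_channels channels (default 24).
#' @param sfreq sampling rate Hz (default 250).
#' @param tmin,tmax epoch span in seconds (defaults -0.15, 1.15).
#' @param n_runs runs (default 8); one miniblock per shape and run.
#' @param snr ratio of planted pattern RMS amplitude to the single-epoch
#'   noise sd (default 0.05, i.e. pattern amplitude is 5% of the noise;
#'   with ~26 reference epochs per condition and run this yields
#'   single-subject within-window whitened correlations around 0.5,
#'   comparable to sensor-level RSA effect sizes).
#' @param noise_sd channel noise standard deviation (default 1).
#' @param noise_cov `"spd"` (random SPD channel covariance, condition number
#'   <= 10; default), `"identity"`, or a matrix.
#' @param oddball list: amp0 (baseline deviance amplitude, in noise-sd
#'   units, default 0.1; peak oddball decoding AUC then spans roughly
#'   0.6-0.8 across shapes), amp_slope (per regularity unit, 0.01), lat0
#'   (onset s, 0.25), lat_slope (s earlier per regularity unit, 0.005),
#'   duration (s, 0.3), direction_jitter (shape-specific deviation of the deviance
#'   direction from the shared component, default 0.3 - oddballs of all
#'   shapes share most of their signature, as required for a decoder trained
#'   on pooled shapes to transfer).
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(model_rdms, windows = list(A = c(0.060, 0.320),
                                                B = c(0.128, 0.400)),
                     regularity = NULL, n_channels = 24, sfreq = 250,
                     tmin = -0.15, tmax = 1.15, n_runs = 8, snr = 0.05,
                     noise_sd = 1, noise_cov = "spd",
                     oddball = list()) {
  stopifnot(length(model_rdms) == 2)
  if (is.null(names(model_rdms))) names(model_rdms) <- c("A", "B")
  labels <- model_rdms[[1]]$labels
  stopifnot(identical(labels, model_rdms[[2]]$labels))
  ob <- utils::modifyList(list(amp0 = 0.1, amp_slope = 0.01, lat0 = 0.25,
                               lat_slope = 0.005, duration = 0.3,
                               direction_jitter = 0.3), oddball)
  if (is.null(regularity)) regularity <- rep(0, length(labels))
  stopifnot(length(regularity) == length(labels))
  for (w in windows) {
    if (w[1] < tmin || w[2] > tmax) stop("window outside the epoch span")
  }
  stopifnot(snr > 0)
  structure(list(model_rdms = model_rdms, windows = windows,
                 regularity = regularity, labels = labels,
                 n_channels = n_channels, sfreq = sfreq, tmin = tmin,
                 tmax = tmax, n_runs = n_runs, snr = snr,
                 noise_sd = noise_sd, noise_cov = noise_cov, oddball = ob),
            class = "sim_spec")
}

#' Simulate an MEG-like oddball epoch set with planted geometry
#'
#' Condition patterns realizing model RDM `A` are active during window A and
#' patterns realizing model `B` during window B (boxcar time courses).
#' Oddball epochs additionally contain a shape-specific deviance pattern
#' whose amplitude grows and whose onset latency shrinks linearly with the
#' shape's regularity. Additive Gaussian channel noise (optionally with a
#' random SPD spatial covariance) is white in time.
#'
#' @param spec a [sim_spec()].
#' @param designs optional list of `design_block`s (one per shape x run);
#'   generated from [make_miniblock_design()] defaults when NULL.
#' @param seed integer seed.
#' @return an [epoch_set]; attributes `"patterns"` (list A/B) and
#'   `"noise_cov"` record the ground truth.
#' @export
simulate_epochs <- function(spec, designs = NULL, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  labels <- spec$labels
  ns <- length(labels)
  times <- seq(spec$tmin, spec$tmax, by = 1 / spec$sfreq)
  nt <- length(times)
  P <- spec$n_channels
  pat <- lapply(seq_along(spec$model_rdms), function(i)
    embed_rdm_patterns(spec$model_rdms[[i]], P, seed = seed + i))
  names(pat) <- names(spec$model_rdms)
  Sigma <- NULL
  if (is.matrix(spec$noise_cov)) Sigma <- spec$noise_cov
  else if (identical(spec$noise_cov, "spd")) Sigma <- random_spd(P, 10, seed + 7)
  chol_S <- if (is.null(Sigma)) NULL else chol(Sigma)

  if (is.null(designs)) {
    designs <- list()
    k <- 0
    for (r in seq_len(spec$n_runs)) for (s in seq_len(ns)) {
      k <- k + 1
      designs[[k]] <- make_miniblock_design(labels[s], block = k,
                                            seed = seed * 10000 + k)
      designs[[k]]$run <- r
    }
  }
  n_items <- sum(vapply(designs, function(d) nrow(d$items), integer(1)))
  amp <- spec$snr * spec$noise_sd
  wA <- times >= spec$windows[[1]][1] & times <= spec$windows[[1]][2]
  wB <- times >= spec$windows[[2]][1] & times <= spec$windows[[2]][2]
  ob <- spec$oddball
  ## per-shape deviance directions: shared component plus shape-specific
  ## jitter, unit RMS per channel
  u <- with_seed(seed + 3, {
    shared <- stats::rnorm(P)
    shared <- shared / sqrt(mean(shared^2))
    m <- matrix(stats::rnorm(ns * P), ns)
    m <- m / sqrt(rowMeans(m^2))
    m <- sweep(ob$direction_jitter * m, 2, shared, `+`)
    m / sqrt(rowMeans(m^2))
  })

  data <- array(0, c(n_items, P, nt))
  info <- data.frame(shape = character(n_items), is_oddball = logical(n_items),
                     run = integer(n_items), block = integer(n_items),
                     position = integer(n_items), direction = NA_integer_,
                     stringsAsFactors = FALSE)
  row <- 0
  reg <- stats::setNames(spec$regularity, labels)
  for (d in designs) {
    s <- match(d$shape, labels)
    base <- t(outer(wA, amp * pat[[1]][s, ]) +
              outer(wB, amp * pat[[2]][s, ]))       # channels x times
    ni <- nrow(d$items)
    rows <- row + seq_len(ni)
    ## all items share the block's condition signal ...
    data[rows, , ] <- rep(base, each = ni)
    ## ... oddballs add the deviance component
    for (it in which(d$items$is_oddball)) {
      a_ob <- (ob$amp0 + ob$amp_slope * reg[d$shape]) * spec$noise_sd
      lat <- max(spec$tmin, ob$lat0 - ob$lat_slope * reg[d$shape])
      wOb <- times >= lat & times <= lat + ob$duration
      data[row + it, , ] <- data[row + it, , ] + t(outer(wOb, a_ob * u[s, ]))
    }
    info$shape[rows] <- d$shape
    info$is_oddball[rows] <- d$items$is_oddball
    info$run[rows] <- if (!is.null(d$run)) d$run else 1L
    info$block[rows] <- d$block
    info$position[rows] <- d$items$position
    info$direction[rows] <- d$items$direction
    row <- row + ni
  }
  noise <- with_seed(seed + 11,
    array(stats::rnorm(n_items * P * nt, sd = spec$noise_sd), c(n_items, P, nt)))
  if (!is.null(chol_S)) {
    flat <- aperm(noise, c(2, 1, 3))
    dim(flat) <- c(P, n_items * nt)
    flat <- t(chol_S) %*% flat
    dim(flat) <- c(P, n_items, nt)
    noise <- aperm(flat, c(2, 1, 3))
  }
  ep <- epoch_set(data + noise, times, info, spec$sfreq)
  attr(ep, "patterns") <- pat
  attr(ep, "noise_cov") <- Sigma
  ep
}

#' Time-resolved crossnobis RDMs from an epoch set
#'
#' Reference (non-oddball) epochs are averaged per condition and run and
#' submitted to the leave-one-run-out crossnobis estimator at each
#' timepoint. The channel noise covariance is estimated once from the
#' epoch-minus-condition-mean residuals (pooled over a subsample of
#' timepoints, shrinkage toward the diagonal).
#'
#' @param epochs an [epoch_set].
#' @param scheme crossnobis fold scheme (default `"loo"`).
#' @param noise `"estimate"` (default), `"identity"`, or a covariance matrix.
#' @param return_precision attach fold-variance entry-precision estimates
#'   for whitened comparison (default FALSE: the miniblock design is
#'   balanced and the sensor noise homoscedastic, so the RDM entries share
#'   one variance and identity precision is the correct whitening).
#' @return list of [rdm]s, one per timepoint.
#' @export
epoch_rdm_series <- function(epochs, scheme = "loo", noise = "estimate",
                             return_precision = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  info <- epochs$info
  keep <- !info$is_oddball
  a <- epochs$data[keep, , , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  shapes <- sort(unique(info$shape))
  runs <- sort(unique(info$run))
  grp <- factor(paste(info$shape, info$run, sep = "\r"),
                levels = as.vector(outer(shapes, runs, paste, sep = "\r")))
  nt <- dim(a)[3]; P <- dim(a)[2]
  Sigma <- NULL
  if (is.matrix(noise)) Sigma <- noise
  else if (identical(noise, "estimate")) {
    tsub <- unique(round(seq(1, nt, length.out = min(nt, 24))))
    res <- do.call(rbind, lapply(tsub, function(t) {
      Xt <- a[, , t]
      mu <- rowsum(Xt, grp, reorder = TRUE) / as.vector(table(grp))
      Xt - mu[as.integer(grp), , drop = FALSE]
    }))
    Sigma <- noise_covariance(res)
  }
  out <- vector("list", nt)
  if (any(table(grp) == 0)) stop("every condition must appear in every run")
  for (t in seq_len(nt)) {
    Xt <- a[, , t]
    mu <- rowsum(Xt, grp, reorder = TRUE) / as.vector(table(grp))
    arr <- array(NA_real_, c(length(shapes), length(runs), P))
    arr[] <- mu[, ]                      # grp levels vary shape fastest
    ps <- pattern_set(arr, labels = shapes)
    out[[t]] <- crossnobis_rdm(ps, scheme = scheme, noise = Sigma,
                               return_precision = return_precision)
  }
  out
}

#' Simulate fMRI-like beta volumes with two planted regions
#'
#' Voxels in region A carry condition patterns realizing model `A`'s RDM,
#' region B realizes model `B`, all other in-mask voxels are pure noise;
#' independent Gaussian noise is added per run.
#'
#' @param model_rdms named list of two model [rdm]s.
#' @param dims grid dimensions (default `c(20, 20, 20)`).
#' @param region_a,region_b logical 3D arrays (disjoint, inside the mask);
#'   defaults: 5x5x5 blocks in opposite octants.
#' @param mask logical 3D array (default: all voxels).
#' @param n_runs runs (default 4).
#' @param snr per-voxel pattern RMS amplitude over noise sd (default 0.3,
#'   which puts single-subject searchlight similarities inside the planted
#'   regions around 0.5-0.6, the scale of reported searchlight effects).
#' @param noise_sd noise standard deviation (default 1).
#' @param n_subjects number of subjects (default 1).
#' @param seed integer seed.
#' @return a [beta_volumes] object, or a list of them when `n_subjects > 1`;
#'   attribute `"regions"` records the planted masks.
#' @export
simulate_beta_volumes <- function(model_rdms, dims = c(20, 20, 20),
                                  region_a = NULL, region_b = NULL,
                                  mask = NULL, n_runs = 4, snr = 0.3,
                                  noise_sd = 1, n_subjects = 1, seed = 1) {
  stopifnot(length(model_rdms) == 2)
  labels <- model_rdms[[1]]$labels
  stopifnot(identical(labels, model_rdms[[2]]$labels))
  if (is.null(mask)) mask <- array(TRUE, dims)
  block_mask <- function(lo) {
    m <- array(FALSE, dims)
    m[lo[1]:(lo[1] + 4), lo[2]:(lo[2] + 4), lo[3]:(lo[3] + 4)] <- TRUE
    m
  }
  if (is.null(region_a)) region_a <- block_mask(c(4, 4, 4))
  if (is.null(region_b)) region_b <- block_mask(dims - 8)
  if (any(region_a & region_b)) stop("planted regions overlap")
  if (any(region_a & !mask) || any(region_b & !mask))
    stop("planted regions must lie inside the mask")
  n_cond <- length(labels)
  idx_a <- which(region_a); idx_b <- which(region_b)
  one_subject <- function(sd_seed) {
    pa <- embed_rdm_patterns(model_rdms[[1]], length(idx_a), seed = sd_seed + 1)
    pb <- embed_rdm_patterns(model_rdms[[2]], length(idx_b), seed = sd_seed + 2)
    data <- with_seed(sd_seed + 3,
      array(stats::rnorm(prod(dims) * n_cond * n_runs, sd = noise_sd),
            c(dims, n_cond, n_runs)))
    flat <- matrix(data, prod(dims))
    amp <- snr * noise_sd
    for (r in seq_len(n_runs)) for (cn in seq_len(n_cond)) {
      col <- (r - 1) * n_cond + cn
      flat[idx_a, col] <- flat[idx_a, col] + amp * pa[cn, ]
      flat[idx_b, col] <- flat[idx_b, col] + amp * pb[cn, ]
    }
    flat[!as.vector(mask), ] <- NA_real_
    data <- array(flat, c(dims, n_cond, n_runs))
    bv <- beta_volumes(data, mask, labels = labels)
    attr(bv, "regions") <- list(A = region_a, B = region_b)
    bv
  }
  if (n_subjects == 1) return(one_subject(seed * 100))
  lapply(seq_len(n_subjects), function(s) one_subject(seed * 100 + s * 17))
}
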