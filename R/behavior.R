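## Behavioral dissimilarity estimation ---------------------------------------
##
## In the visual-search task, each trial shows several exemplars of a
## reference shape plus one intruder; easy search (high accuracy, fast
## responses) means the two shapes are dissimilar. The empirical
## dissimilarity of an ordered pair is the average success rate divided by
## the average response time; ordered estimates are averaged into an
## unordered value (no prediction for search asymmetries) and finally
## z-scored across the off-diagonal entries.

#' Assemble a trial table
#'
#' @param participant,reference,intruder,correct,rt column vectors; `rt` in
#'   milliseconds.
#' @return validated data.frame of class `trial_table`.
#' @export
trial_table <- function(participant, reference, intruder, correct, rt) {
  df <- data.frame(participant = participant, reference = as.character(reference),
                   intruder = as.character(intruder),
                   correct = as.logical(correct), rt = as.numeric(rt))
  validate_trials(df)
}

#' Validate a trial data.frame
#' @param df data.frame with columns participant, reference, intruder,
#'   correct, rt.
#' @return the data.frame, invisibly classed as `trial_table`.
#' @export
validate_trials <- function(df) {
  need <- c("participant", "reference", "intruder", "correct", "rt")
  if (!all(need %in% names(df)))
    stop("missing trial columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$reference == df$intruder)) stop("reference must differ from intruder")
  if (any(!is.finite(df$rt)) || any(df$rt <= 0)) stop("rt must be finite and positive")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Empirical behavioral RDM from visual-search trials
#'
#' With `pool = TRUE` (the default), trials are pooled across participants
#' before forming the accuracy/RT ratio: for each ordered (reference,
#' intruder) pair, dissimilarity = mean(correct) / mean(rt); the two ordered
#' estimates are averaged, and the resulting unordered entries are z-scored.
#' With `pool = FALSE` a list of per-participant RDMs is returned (single
#' trials give 0 or 1/RT); these are kept raw (never z-scored per
#' participant).
#'
#' @param trials trial data.frame (see [validate_trials()]).
#' @param labels condition labels; defaults to the sorted union of shapes.
#' @param pool pool participants before the ratio (default TRUE).
#' @param zscore z-score the pooled unordered entries (default TRUE).
#' @param include_error_rt include error-trial RTs in the RT average
#'   (default TRUE).
#' @return a `behavioral_rdm` (subclass of [rdm]) with fields `raw_values`
#'   and `n_trials`, or a list of them when `pool = FALSE`.
#' @export
empirical_rdm <- function(trials, labels = NULL, pool = TRUE, zscore = TRUE,
                          include_error_rt = TRUE) {
  trials <- validate_trials(as.data.frame(trials))
  if (is.null(labels)) labels <- sort(unique(c(trials$reference, trials$intruder)))
  if (!pool) {
    sp <- split(trials, trials$participant)
    return(lapply(sp, empirical_rdm, labels = labels, pool = TRUE,
                  zscore = FALSE, include_error_rt = include_error_rt))
  }
  n <- length(labels)
  acc <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  rtm <- acc; cnt <- matrix(0L, n, n, dimnames = list(labels, labels))
  key <- interaction(factor(trials$reference, labels),
                     factor(trials$intruder, labels), drop = FALSE)
  agg_acc <- tapply(trials$correct, key, mean)
  agg_rt <- if (include_error_rt) tapply(trials$rt, key, mean) else
    tapply(seq_len(nrow(trials)), key, function(i) {
      ok <- trials$correct[i]
      if (!any(ok)) NA_real_ else mean(trials$rt[i][ok])
    })
  agg_n <- tapply(trials$rt, key, length)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- paste(labels[i], labels[j], sep = ".")
    if (!is.na(agg_n[k])) {
      acc[i, j] <- agg_acc[k]; rtm[i, j] <- agg_rt[k]; cnt[i, j] <- agg_n[k]
    }
  }
  ordered <- acc / rtm
  pairs <- utils::combn(n, 2)
  raw <- numeric(ncol(pairs)); ntr <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    vals <- c(ordered[i, j], ordered[j, i])
    if (all(is.na(vals))) stop(sprintf("no trials for pair (%s, %s)",
                                       labels[i], labels[j]))
    raw[k] <- mean(vals, na.rm = TRUE)
    ntr[k] <- cnt[i, j] + cnt[j, i]
  }
  vals <- raw
  if (zscore) {
    s <- stats::sd(raw)
    if (length(raw) > 1 && s > 0) {
      vals <- (raw - mean(raw)) / s
    } else {
      warning("all dissimilarity entries identical; z-scores set to 0")
      vals <- rep(0, length(raw))
    }
  }
  out <- rdm(vals, labels, metric = if (zscore) "accuracy/rt (z)" else "accuracy/rt")
  out$raw_values <- raw
  out$n_trials <- ntr
  class(out) <- c("behavioral_rdm", class(out))
  out
}

#' Multiple regression of an empirical RDM on model RDMs
#'
#' Ordinary least squares with intercept on the vectorized unordered
#' entries. Model RDM vectors are standardized (z-scored) by default so
#' coefficients are comparable across models. When `per_unit` supplies
#' per-participant RDMs, the regression is also fit per participant and the
#' first two models' coefficients are compared with a paired t-test.
#'
#' @param empirical an [rdm].
#' @param models named list of model [rdm]s over the same labels.
#' @param per_unit optional list of per-participant [rdm]s.
#' @param standardize z-score model predictors (default TRUE).
#' @return list with `coefficients` (named, without intercept), `r_squared`,
#'   `fit` (the `lm` object), and with `per_unit`: `unit_coefficients`,
#'   `comparison` (paired t-test), `weight_ratio` (mean coef 1 / mean coef 2).
#' @export
rdm_regression <- function(empirical, models, per_unit = NULL,
                           standardize = TRUE) {
  stopifnot(inherits(empirical, "rdm"))
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  X <- sapply(models, function(m) {
    stopifnot(inherits(m, "rdm"))
    if (!identical(m$labels, empirical$labels)) m <- subset_rdm(m, empirical$labels)
    m$values
  })
  if (standardize) X <- scale(X)
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("rank-deficient model design")
  df <- data.frame(y = empirical$values, X)
  names(df) <- c("y", names(models))
  fit <- stats::lm(y ~ ., data = df)
  out <- list(coefficients = stats::coef(fit)[-1],
              r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit)
  if (!is.null(per_unit)) {
    co <- t(vapply(per_unit, function(u) {
      if (!identical(u$labels, empirical$labels)) u <- subset_rdm(u, empirical$labels)
      dfu <- data.frame(y = u$values, X)
      names(dfu) <- names(df)
      stats::coef(stats::lm(y ~ ., data = dfu))[-1]
    }, numeric(length(models))))
    colnames(co) <- names(models)
    out$unit_coefficients <- co
    if (length(models) >= 2) {
      out$comparison <- stats::t.test(co[, 1], co[, 2], paired = TRUE)
      out$weight_ratio <- mean(co[, 1]) / mean(co[, 2])
    }
  }
  out
}

#' Two-dimensional ordinal (non-metric) multidimensional scaling
#'
#' Wraps `MASS::isoMDS` with multiple seeded random restarts, returning the
#' configuration with the lowest stress. Dissimilarities are shifted to be
#' positive when needed (a monotone transform, irrelevant for ordinal MDS).
#'
#' @param x an [rdm].
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts in addition to the classical-scaling
#'   start (default 32).
#' @param seed integer seed.
#' @return list with `points` (n x k, labeled rows), `stress` (fraction,
#'   0 = perfect), and `rdm` labels.
#' @export
mds_embed <- function(x, k = 2, n_restarts = 32, seed = 1) {
  stopifnot(inherits(x, "rdm"))
  n <- n_conditions(x)
  if (n < k + 1) stop("need at least k+1 conditions")
  m <- as.matrix(x)
  off <- m[upper.tri(m)]
  if (min(off) <= 0) {
    shift <- -min(off) + 0.05 * (max(off) - min(off)) + 1e-6
    m[upper.tri(m)] <- off + shift
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  diag(m) <- 0
  d <- stats::as.dist(m)
  best <- NULL
  with_seed(seed, {
    starts <- c(list(stats::cmdscale(d, k = k)),
                lapply(seq_len(n_restarts), function(i)
                  matrix(stats::rnorm(n * k), n, k)))
    for (s in starts) {
      fit <- tryCatch(
        suppressWarnings(MASS::isoMDS(d, y = s, k = k, trace = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
        best <- fit
    }
  })
  if (is.null(best)) stop("MDS failed to converge from any start")
  pts <- best$points
  rownames(pts) <- x$labels
  list(points = pts, stress = best$stress / 100, labels = x$labels)
}

#' Project a per-condition property onto an MDS embedding
#'
#' Regresses the property (e.g. the number of geometric features of each
#' shape) on the embedding axes.
#'
#' @param coords n x k matrix of MDS coordinates.
#' @param property numeric vector of length n.
#' @return list with `coefficients` (per axis), `direction` (unit vector in
#'   embedding space), and the `lm` fit.
#' @export
project_property <- function(coords, property) {
  stopifnot(is.matrix(coords), length(property) == nrow(coords))
  if (stats::sd(property) == 0) stop("property has zero variance")
  fit <- stats::lm(property ~ coords)
  b <- stats::coef(fit)[-1]
  list(coefficients = b, direction = b / sqrt(sum(b^2)), fit = fit)
}

#' Bootstrap significance of a property projection
#'
#' Resamples participants' trial sets with replacement, recomputes the
#' pooled empirical RDM, re-embeds it (aligning each bootstrap embedding to
#' the point-estimate embedding by Procrustes rotation), re-projects the
#' property, and reports two-sided percentile p-values per axis.
#'
#' @param trials trial data.frame.
#' @param property per-condition numeric vector (in label order of the
#'   pooled RDM).
#' @param n_boot bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param mds_restarts restarts per bootstrap embedding (default 4).
#' @return list with `estimate` (axis coefficients), `p` (per axis),
#'   `boot_coefficients` (n_boot x k), and `embedding`.
#' @export
bootstrap_projection <- function(trials, property, n_boot = 500, seed = 1,
                                 mds_restarts = 4) {
  trials <- validate_trials(as.data.frame(trials))
  ref_rdm <- empirical_rdm(trials)
  emb <- mds_embed(ref_rdm, seed = seed)
  est <- project_property(emb$points, property)
  ids <- unique(trials$participant)
  sp <- split(seq_len(nrow(trials)), trials$participant)
  bc <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(sp[as.character(take)], use.names = FALSE)
      r <- empirical_rdm(trials[idx, , drop = FALSE], labels = ref_rdm$labels)
      e <- mds_embed(r, n_restarts = mds_restarts, seed = seed + b)
      pts <- procrustes_align(emb$points, e$points)
      project_property(pts, property)$coefficients
    }, numeric(ncol(emb$points))))
  })
  p <- vapply(seq_len(ncol(bc)), function(j) {
    lo <- mean(bc[, j] <= 0); hi <- mean(bc[, j] >= 0)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  list(estimate = est$coefficients, p = p, boot_coefficients = bc,
       embedding = emb)
}

#' Orthogonal Procrustes alignment of one configuration to another
#'
#' Aligns `y` to `x` by translation, rotation/reflection and uniform scaling
#' (least squares).
#' @param x,y n x k coordinate matrices.
#' @return aligned version of `y`.
#' @export
procrustes_align <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  R <- s$v %*% t(s$u)
  sc <- sum(s$d) / sum(yc^2)
  sweep(sc * (yc %*% R), 2, colMeans(x), `+`)
}
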