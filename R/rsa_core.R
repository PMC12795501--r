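## Crossnobis distances and whitened RDM comparison -------------------------
##
## Condition patterns measured in independent folds (runs) are compared with
## the cross-validated Mahalanobis distance ("crossnobis"): products of
## pattern differences from independent folds, so that additive noise cancels
## in expectation and the estimator is unbiased (within-condition distances
## average zero, and estimates may legitimately be negative). Distances are
## normalized by the channel count so values are comparable across sphere or
## sensor counts. Empirical and model RDMs are compared with a whitened
## Pearson correlation: both RDM vectors are multiplied by the matrix square
## root of an entry-precision estimate before correlating.

#' Bundle condition patterns measured across folds
#'
#' @param data numeric array `conditions x folds x channels`.
#' @param labels condition labels (default: dimnames or `c1..cn`).
#' @param residuals optional matrix `samples x channels` of noise residuals
#'   used to estimate the noise covariance.
#' @return object of class `pattern_set`.
#' @export
pattern_set <- function(data, labels = NULL, residuals = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] < 2) stop("need at least 2 folds")
  if (is.null(labels)) labels <- dimnames(data)[[1]]
  if (is.null(labels)) labels <- paste0("c", seq_len(dim(data)[1]))
  if (length(labels) != dim(data)[1]) stop("labels/data mismatch")
  if (!all(is.finite(data))) stop("patterns must be finite; missing conditions in a fold?")
  if (!is.null(residuals)) stopifnot(is.matrix(residuals), ncol(residuals) == dim(data)[3])
  structure(list(data = data, labels = labels, residuals = residuals),
            class = "pattern_set")
}

#' Shrinkage estimate of the channel noise covariance
#'
#' Sample covariance shrunk toward its diagonal. With `shrinkage = "auto"`
#' the shrinkage intensity is the analytic optimum of Schafer & Strimmer
#' (ratio of summed estimated variances of the off-diagonal covariances to
#' their summed squares); `shrinkage = 1` returns the diagonal matrix,
#' `shrinkage = 0` the raw sample covariance. A small ridge guarantees
#' positive definiteness.
#'
#' @param residuals matrix `samples x channels`.
#' @param shrinkage `"auto"` or a number in `[0, 1]`.
#' @return channels x channels symmetric positive-definite matrix, with the
#'   chosen intensity in attribute `"lambda"`.
#' @export
noise_covariance <- function(residuals, shrinkage = "auto") {
  stopifnot(is.matrix(residuals))
  if (!all(is.finite(residuals))) stop("residuals must be finite")
  n <- nrow(residuals); P <- ncol(residuals)
  if (n < 2) stop("need at least 2 residual samples")
  S <- stats::cov(residuals)
  if (identical(shrinkage, "auto")) {
    Xc <- sweep(residuals, 2, colMeans(residuals))
    lambda <- 0
    off <- upper.tri(S)
    denom <- sum(S[off]^2)
    if (denom > 0) {
      ## var of each off-diagonal covariance estimate
      wbar <- crossprod(Xc) / n
      v <- matrix(0, P, P)
      for (k in seq_len(n)) {
        wk <- tcrossprod(Xc[k, ])
        v <- v + (wk - wbar)^2
      }
      varS <- n / ((n - 1)^3) * v
      lambda <- min(1, max(0, sum(varS[off]) / denom))
    }
  } else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    lambda <- shrinkage
  }
  Sig <- lambda * diag(diag(S), P) + (1 - lambda) * S
  Sig <- Sig + diag(1e-10 * mean(diag(Sig)) + 1e-12, P)
  attr(Sig, "lambda") <- lambda
  Sig
}

## shared crossnobis kernel: folds = list of (conditions x channels) pattern
## matrices; returns the choose(n,2) vector of cross-validated distances.
## whiten: channels x channels matrix W with W W' = Sigma^-1 (identity if NULL)
.crossnobis_core <- function(folds, scheme = c("all-pairs", "loo"),
                             whiten = NULL, normalize = TRUE,
                             per_fold = FALSE) {
  scheme <- match.arg(scheme)
  M <- length(folds)
  n <- nrow(folds[[1]])
  P <- ncol(folds[[1]])
  C <- .pair_contrasts(n)
  D <- lapply(folds, function(x) {
    xw <- if (is.null(whiten)) x else x %*% whiten
    C %*% xw                                  # pairwise differences
  })
  contrib <- NULL
  if (scheme == "all-pairs") {
    cnt <- M * (M - 1) / 2
    contrib <- matrix(0, choose(n, 2), cnt)
    c2 <- 0
    for (m in seq_len(M - 1)) for (k in (m + 1):M) {
      c2 <- c2 + 1
      contrib[, c2] <- rowSums(D[[m]] * D[[k]])
    }
  } else {
    tot <- Reduce(`+`, D)
    contrib <- sapply(seq_len(M), function(m)
      rowSums(D[[m]] * (tot - D[[m]])) / (M - 1))
  }
  if (normalize) contrib <- contrib / P
  acc <- rowMeans(contrib)
  if (per_fold) list(values = acc, contrib = contrib) else acc
}

.pair_contrasts <- function(n) {
  idx <- utils::combn(n, 2)
  C <- matrix(0, ncol(idx), n)
  C[cbind(seq_len(ncol(idx)), idx[1, ])] <- 1
  C[cbind(seq_len(ncol(idx)), idx[2, ])] <- -1
  C
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For conditions i, j and independent folds m != n, the distance is the
#' average of `(x_i^m - x_j^m)' Sigma^-1 (x_i^n - x_j^n) / P` over fold
#' pairs (`scheme = "all-pairs"`) or over left-out folds against the mean of
#' the remaining folds (`scheme = "loo"`). Estimates are unbiased and may be
#' negative; they are never clipped.
#'
#' @param patterns a [pattern_set].
#' @param scheme cross-validation scheme over folds.
#' @param noise noise covariance matrix `Sigma` (channels x channels). If
#'   `NULL`, it is estimated from the pattern-set residuals when present
#'   (with auto shrinkage) and is the identity otherwise, in which case the
#'   metric degrades to cross-validated Euclidean.
#' @param normalize divide by the channel count `P` (default TRUE).
#' @param return_precision attach a diagonal entry-precision estimate
#'   (inverse variance of the per-fold distance contributions) for later
#'   whitened comparison. Note that under balanced designs with
#'   homoscedastic noise the true entry variances are equal, so identity
#'   precision (the default downstream) is already the correct whitening;
#'   the fold-variance estimate is useful for unbalanced or heteroscedastic
#'   data.
#' @param precision_shrink shrinkage of the entry variances toward their
#'   mean, `v' = v + precision_shrink * mean(v)` (default 1). Shrinkage
#'   limits the coupling between estimated weights and the values
#'   themselves, which would otherwise bias whitened correlations toward
#'   negative values.
#' @return an [rdm] with metric `"crossnobis"`.
#' @export
crossnobis_rdm <- function(patterns, scheme = c("all-pairs", "loo"),
                           noise = NULL, normalize = TRUE,
                           return_precision = FALSE, precision_shrink = 1) {
  stopifnot(inherits(patterns, "pattern_set"))
  scheme <- match.arg(scheme)
  dm <- patterns$data
  M <- dim(dm)[2]
  if (is.null(noise) && !is.null(patterns$residuals))
    noise <- noise_covariance(patterns$residuals)
  W <- NULL
  if (!is.null(noise)) {
    R <- tryCatch(chol(noise), error = function(e)
      stop("noise covariance is not positive definite; use shrinkage"))
    W <- backsolve(R, diag(nrow(noise)))   # W W' = Sigma^-1
  }
  folds <- lapply(seq_len(M), function(m)
    matrix(dm[, m, ], nrow = dim(dm)[1], ncol = dim(dm)[3]))
  res <- .crossnobis_core(folds, scheme = scheme, whiten = W,
                          normalize = normalize, per_fold = return_precision)
  prec <- NULL
  if (return_precision) {
    ## entry precision = inverse variance of the mean of the per-fold
    ## distance contributions (diagonal approximation)
    k <- ncol(res$contrib)
    v <- apply(res$contrib, 1, stats::var) / k
    v <- v + precision_shrink * mean(v)
    prec <- 1 / pmax(v, .Machine$double.eps)
    res <- res$values
  }
  rdm(res, patterns$labels, metric = "crossnobis", precision = prec)
}

#' Whitened correlation between two RDMs
#'
#' Pearson correlation of the two RDM vectors after multiplying both by the
#' matrix square root of an entry-precision estimate. With identity
#' precision this is the plain Pearson correlation; it is invariant to
#' positive rescaling of either RDM.
#'
#' @param empirical,model [rdm]s over the same labels.
#' @param precision overrides the precision carried by `empirical`: a vector
#'   (diagonal) or full matrix over RDM entries; `NULL` falls back to
#'   `empirical$precision`, then to the identity.
#' @return correlation in `[-1, 1]`, or `NA` if a whitened vector has zero
#'   variance.
#' @export
whitened_rdm_similarity <- function(empirical, model, precision = NULL) {
  stopifnot(inherits(empirical, "rdm"), inherits(model, "rdm"))
  if (!identical(empirical$labels, model$labels)) {
    if (!setequal(empirical$labels, model$labels))
      stop("RDMs have different label sets")
    model <- subset_rdm(model, empirical$labels)
  }
  x <- empirical$values; y <- model$values
  if (is.null(precision)) precision <- empirical$precision
  if (!is.null(precision)) {
    if (is.matrix(precision)) {
      e <- eigen(precision, symmetric = TRUE)
      Wh <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
      x <- drop(Wh %*% x); y <- drop(Wh %*% y)
    } else {
      w <- sqrt(precision)
      x <- w * x; y <- w * y
    }
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance whitened RDM vector")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Compare a series of empirical RDMs with each model separately
#'
#' The model RDMs are treated as effectively orthogonal and compared one at
#' a time (no cross-model partialling).
#'
#' @param empirical list of [rdm]s (e.g. one per timepoint or location).
#' @param models named list of model [rdm]s.
#' @param precision see [whitened_rdm_similarity()].
#' @return matrix `length(empirical) x length(models)` of similarities.
#' @export
compare_models_separately <- function(empirical, models, precision = NULL) {
  stopifnot(is.list(empirical), is.list(models))
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  out <- sapply(models, function(m)
    vapply(empirical, whitened_rdm_similarity, numeric(1), model = m,
           precision = precision))
  matrix(out, nrow = length(empirical), ncol = length(models),
         dimnames = list(NULL, names(models)))
}
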