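## Time-resolved oddball decoding ---------------------------------------------
##
## Epochs from an oddball stream (miniblocks of one repeated reference shape
## with rare corner-displaced deviants) are classified as reference vs
## oddball at each timepoint with an L2-regularized logistic regression on
## the channel vector. Cross-validation uses three partitions of the runs
## (even vs odd, first vs second half, runs {1,2,5,6} vs {3,4,7,8}), each in
## both directions, giving six train/test splits. Performance is the ROC
## area under the curve, computed per shape on the held-out runs (robust to
## the 4:26 class imbalance).

#' Construct an epoch set
#'
#' @param data numeric array `epochs x channels x timepoints`.
#' @param times timepoint vector in seconds (strictly increasing).
#' @param info data.frame with one row per epoch: `shape`, `is_oddball`,
#'   `run`, `block`, `position` (1-based within-block position).
#' @param sfreq sampling rate in Hz.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, info, sfreq) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) stop("times/data mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  need <- c("shape", "is_oddball", "run", "block", "position")
  if (!all(need %in% names(info)))
    stop("missing epoch metadata: ", paste(setdiff(need, names(info)), collapse = ", "))
  if (nrow(info) != dim(data)[1]) stop("info/data mismatch")
  structure(list(data = data, times = times, info = info, sfreq = sfreq),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d timepoints (%g Hz), %d oddballs\n",
              d[1], d[2], d[3], x$sfreq, sum(x$info$is_oddball)))
  invisible(x)
}

#' Drop the first k epochs of every block
#'
#' Block-initial trials are uninformative for oddball detection: they can
#' never be oddballs, and with no explicit block transition they act as
#' oddballs of the previous block's shape.
#'
#' @param epochs an [epoch_set].
#' @param k number of initial positions to drop (default 6).
#' @return the reduced [epoch_set].
#' @export
drop_block_initial <- function(epochs, k = 6) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$info$position > k
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$times,
            epochs$info[keep, , drop = FALSE], epochs$sfreq)
}

#' Decoding configuration
#'
#' @param latency_threshold AUC level defining the decoding latency
#'   (default 0.57).
#' @param smooth_ms width of the uniform smoothing window in ms (default
#'   100; 0 disables smoothing).
#' @param lambda ridge penalty of the logistic decoder (default 0.01).
#' @param normalize `"channels"` (z-score each epoch's channel vector per
#'   timepoint, default) or `"window"` (scale each epoch by its whole-window
#'   mean/sd).
#' @param per_shape_training train one decoder per shape instead of pooling
#'   shapes for training (default FALSE).
#' @return list of class `decode_config`.
#' @export
decode_config <- function(latency_threshold = 0.57, smooth_ms = 100,
                          lambda = 0.01,
                          normalize = c("channels", "window"),
                          per_shape_training = FALSE) {
  stopifnot(latency_threshold > 0.5, latency_threshold < 1, smooth_ms >= 0)
  structure(list(latency_threshold = latency_threshold, smooth_ms = smooth_ms,
                 lambda = lambda, normalize = match.arg(normalize),
                 per_shape_training = per_shape_training),
            class = "decode_config")
}

#' Six train/test splits over runs
#'
#' Three partitions of the (sorted) runs - even vs odd, first vs second
#' half, and the interleaved-pairs split {1,2,5,6} vs {3,4,7,8} - each used
#' in both directions.
#'
#' @param runs vector of run identifiers (8 runs expected; other even counts
#'   use the same three partition rules by run rank).
#' @return list of 6 lists with elements `train` and `test` (run ids).
#' @export
make_run_folds <- function(runs) {
  u <- sort(unique(runs))
  m <- length(u)
  if (m < 4 || m %% 2 != 0) stop("fold scheme needs an even number (>= 4) of runs")
  r <- seq_len(m)
  parts <- list(even_odd = r %% 2 == 0,
                halves = r > m / 2,
                pairs = ((r - 1) %/% 2) %% 2 == 1)
  out <- list()
  for (p in parts) {
    out[[length(out) + 1]] <- list(train = u[p], test = u[!p])
    out[[length(out) + 1]] <- list(train = u[!p], test = u[p])
  }
  out
}

## ridge-penalized logistic regression (IRLS); intercept unpenalized
.ridge_logistic <- function(X, y, lambda = 0.01, max_iter = 50, tol = 1e-8) {
  Xa <- cbind(1, X)
  p <- ncol(Xa)
  pen <- c(0, rep(lambda, p - 1))
  w <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% w)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa, wt * Xa)
    diag(H) <- diag(H) + pen
    g <- crossprod(Xa, y - mu) - pen * w
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    w <- w + step
    if (max(abs(step)) < tol) break
  }
  w
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) estimator; invariant to strictly monotone
#' transformations of the scores.
#' @param scores numeric decision values.
#' @param labels logical (TRUE = positive class).
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## per-epoch normalization; a: epochs x channels x times
.normalize_epochs <- function(a, how = "channels") {
  d <- dim(a)
  if (how == "channels") {
    ## z-score across channels, separately per epoch and timepoint
    m <- aperm(a, c(2, 1, 3))                 # channels x epochs x times
    dim(m) <- c(d[2], d[1] * d[3])
    mu <- colMeans(m)
    sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 1e-24))
    m <- (m - rep(mu, each = d[2])) / rep(sdv, each = d[2])
    dim(m) <- c(d[2], d[1], d[3])
    aperm(m, c(2, 1, 3))
  } else {
    ## scale each epoch by its whole-window mean and sd
    flat <- matrix(a, d[1])
    mu <- rowMeans(flat)
    sdv <- sqrt(pmax(rowMeans(flat^2) - mu^2, 1e-24))
    array((a - mu) / sdv, d)
  }
}

#' Time-resolved reference-vs-oddball decoding
#'
#' At each timepoint, a ridge logistic regression is trained on the channel
#' vectors of all shapes jointly (or per shape with
#' `config$per_shape_training`) and tested separately on each shape's
#' held-out epochs; performance is the ROC AUC averaged over the six run
#' splits. Each epoch is normalized before fitting. Block-initial epochs
#' should be removed first (see [drop_block_initial()]).
#'
#' @param epochs an [epoch_set].
#' @param config a [decode_config()].
#' @return list with `auc` (shapes x timepoints, smoothed if configured),
#'   `auc_raw` (unsmoothed), `times`, `shapes`, `config`.
#' @export
time_resolved_oddball_decode <- function(epochs, config = decode_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  info <- epochs$info
  shapes <- sort(unique(info$shape))
  folds <- make_run_folds(info$run)
  a <- .normalize_epochs(epochs$data, config$normalize)
  nt <- dim(a)[3]
  y <- info$is_oddball
  auc <- array(NA_real_, c(length(shapes), nt, length(folds)))
  for (f in seq_along(folds)) {
    tr <- info$run %in% folds[[f]]$train
    te <- !tr
    te_shape <- lapply(shapes, function(s) which(te & info$shape == s))
    for (t in seq_len(nt)) {
      Xt <- a[, , t]
      if (config$per_shape_training) {
        for (si in seq_along(shapes)) {
          trs <- tr & info$shape == shapes[si]
          if (length(unique(y[trs])) < 2) next
          w <- .ridge_logistic(Xt[trs, , drop = FALSE], y[trs], config$lambda)
          idx <- te_shape[[si]]
          sc <- drop(cbind(1, Xt[idx, , drop = FALSE]) %*% w)
          auc[si, t, f] <- auc_score(sc, y[idx])
        }
      } else {
        if (length(unique(y[tr])) < 2) next
        w <- .ridge_logistic(Xt[tr, , drop = FALSE], y[tr], config$lambda)
        sc_all <- drop(cbind(1, Xt) %*% w)
        for (si in seq_along(shapes)) {
          idx <- te_shape[[si]]
          auc[si, t, f] <- auc_score(sc_all[idx], y[idx])
        }
      }
    }
  }
  auc_raw <- apply(auc, c(1, 2), mean)   # NA propagates: no imputation
  dimnames(auc_raw) <- list(shapes, NULL)
  out <- auc_raw
  if (config$smooth_ms > 0)
    out <- t(apply(auc_raw, 1, sliding_average,
                   window_ms = config$smooth_ms, sfreq = epochs$sfreq))
  list(auc = out, auc_raw = auc_raw, times = epochs$times, shapes = shapes,
       config = config)
}

#' Centered uniform moving average with truncated edges
#'
#' @param x numeric series.
#' @param window_ms window width in milliseconds.
#' @param sfreq sampling rate in Hz.
#' @return smoothed series, same length.
#' @export
sliding_average <- function(x, window_ms = 100, sfreq) {
  w <- round(window_ms / 1000 * sfreq)
  if (w <= 1) return(x)
  n <- length(x)
  half_lo <- floor((w - 1) / 2); half_hi <- ceiling((w - 1) / 2)
  nas <- is.na(x)
  x0 <- x; x0[nas] <- 0
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(!nas))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  num <- cs[hi + 1] - cs[lo]
  den <- cn[hi + 1] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Correlate decoding performance with geometric regularity over time
#'
#' For each participant, the per-shape AUC at each timepoint is correlated
#' (Pearson) with the per-shape regularity predictor; the per-participant
#' correlation series are then submitted to a one-tailed temporal cluster
#' test.
#'
#' @param auc_list list of `shapes x timepoints` AUC matrices, one per
#'   participant (shared shape order).
#' @param regularity per-shape numeric predictor (feature counts, or an
#'   empirical difficulty vector).
#' @param alpha,n_perm,seed passed to [temporal_cluster_test()].
#' @return list with `r` (participants x timepoints) and `test`.
#' @export
regularity_correlation <- function(auc_list, regularity, alpha = 0.05,
                                   n_perm = 2^13, seed = 1) {
  if (stats::sd(regularity) == 0) stop("regularity predictor is constant")
  if (length(regularity) < 3) stop("need at least 3 shapes")
  r <- t(vapply(auc_list, function(a) {
    stopifnot(nrow(a) == length(regularity))
    suppressWarnings(as.numeric(stats::cor(a, regularity,
                                           use = "pairwise.complete.obs")))
  }, numeric(ncol(auc_list[[1]]))))
  test <- temporal_cluster_test(r, alpha = alpha, n_perm = n_perm,
                                tail = "greater", seed = seed)
  list(r = r, test = test)
}

#' Decoding latency per shape
#'
#' First post-onset time sample at which the (smoothed) AUC exceeds the
#' threshold; `NA` when the series never exceeds it.
#'
#' @param auc `shapes x timepoints` matrix.
#' @param times timepoints in seconds.
#' @param threshold AUC threshold (default 0.57).
#' @return named latency vector (seconds).
#' @export
decode_latency <- function(auc, times, threshold = 0.57) {
  post <- which(times >= 0)
  vapply(seq_len(nrow(auc)), function(i) {
    k <- which(auc[i, post] > threshold)
    if (!length(k)) NA_real_ else times[post[k[1]]]
  }, numeric(1)) |> stats::setNames(rownames(auc))
}

#' One-tailed group test of the latency-regularity slope
#'
#' Each participant's latencies are regressed on the regularity predictor;
#' the slopes are tested against zero with a one-tailed t-test in the
#' direction "more regular -> earlier" (negative slope).
#'
#' @param latencies matrix `participants x shapes` (NA allowed; participants
#'   with fewer than 3 defined latencies are excluded with a warning).
#' @param regularity per-shape predictor.
#' @return list with `slopes`, `test` (htest), `excluded`.
#' @export
latency_slope_test <- function(latencies, regularity) {
  stopifnot(ncol(latencies) == length(regularity))
  slopes <- apply(latencies, 1, function(l) {
    ok <- is.finite(l)
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm(l[ok] ~ regularity[ok]))[2]
  })
  excluded <- which(!is.finite(slopes))
  if (length(excluded))
    warning(sprintf("%d participant(s) excluded (undefined latencies)",
                    length(excluded)))
  sl <- slopes[is.finite(slopes)]
  list(slopes = slopes,
       test = stats::t.test(sl, mu = 0, alternative = "less"),
       excluded = excluded)
}
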