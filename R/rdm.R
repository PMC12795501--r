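## RDM container -----------------------------------------------------------
##
## A representational dissimilarity matrix is stored as its strict upper
## triangle in column-pair order (1,2), (1,3), ..., (1,n), (2,3), ... —
## the order produced by utils::combn(n, 2). Values may be negative
## (cross-validated distance estimates are unbiased, not non-negative).

#' Construct an RDM from a vector of pairwise dissimilarities
#'
#' @param values numeric vector of length `choose(n, 2)` in `combn(n, 2)`
#'   pair order.
#' @param labels character vector of `n` unique condition labels.
#' @param metric string tag recording how the values were computed.
#' @param precision optional per-entry precision: a vector of length
#'   `choose(n, 2)` (diagonal approximation) or a full matrix; used by
#'   [whitened_rdm_similarity()].
#' @return object of class `rdm`.
#' @export
rdm <- function(values, labels, metric = "unknown", precision = NULL) {
  n <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  if (length(values) != choose(n, 2))
    stop(sprintf("expected %d values for %d labels, got %d",
                 choose(n, 2), n, length(values)))
  if (!all(is.finite(values))) stop("RDM values must be finite")
  if (!is.null(precision)) {
    ok <- (is.matrix(precision) && all(dim(precision) == length(values))) ||
      (is.numeric(precision) && length(precision) == length(values))
    if (!ok) stop("precision has wrong dimensions")
  }
  structure(list(values = as.numeric(values), labels = as.character(labels),
                 metric = metric, precision = precision),
            class = "rdm")
}

#' Number of conditions of an RDM
#' @param x an `rdm`.
#' @export
n_conditions <- function(x) length(x$labels)

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, %d entries, metric '%s'%s\n",
              n_conditions(x), length(x$values), x$metric,
              if (!is.null(x$precision)) ", with entry precision" else ""))
  invisible(x)
}

#' @export
as.matrix.rdm <- function(x, ...) {
  n <- n_conditions(x)
  m <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  idx <- utils::combn(n, 2)
  for (k in seq_len(ncol(idx))) {
    m[idx[1, k], idx[2, k]] <- x$values[k]
    m[idx[2, k], idx[1, k]] <- x$values[k]
  }
  diag(m) <- 0
  m
}

#' Build an RDM from a symmetric square matrix
#'
#' @param m square numeric matrix; asymmetries beyond `tol` are an error,
#'   smaller ones are symmetrized away.
#' @param labels condition labels; defaults to `rownames(m)`.
#' @param metric metric tag.
#' @param tol maximum tolerated absolute asymmetry (default 1e-9).
#' @export
rdm_from_matrix <- function(m, labels = rownames(m), metric = "unknown",
                            tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) stop("matrix is asymmetric beyond tolerance")
  if (is.null(labels)) labels <- paste0("c", seq_len(nrow(m)))
  m <- (m + t(m)) / 2
  rdm(upper_vec(m), labels, metric = metric)
}

#' Restrict an RDM to a subset of conditions
#'
#' @param x an `rdm`.
#' @param labels labels to keep, in the desired order.
#' @return the sub-RDM over `labels`.
#' @export
subset_rdm <- function(x, labels) {
  if (!all(labels %in% x$labels)) stop("unknown labels in subset")
  m <- as.matrix(x)[labels, labels, drop = FALSE]
  out <- rdm_from_matrix(m, labels, metric = x$metric)
  out
}

#' Vectorize the upper triangle of a square matrix in combn pair order
#' @keywords internal
upper_vec <- function(m) {
  n <- nrow(m)
  idx <- utils::combn(n, 2)
  m[cbind(idx[1, ], idx[2, ])]
}
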