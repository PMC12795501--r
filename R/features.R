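## Discrete geometric feature code -----------------------------------------
##
## A quadrilateral is encoded by 22 binary regularity features: 4 right
## angles (one per vertex), 6 pairwise angle equalities, 6 pairwise side
## equalities, and 6 pairwise side parallelisms, all evaluated up to a
## dimensionless tolerance (default 12.5%). The tolerance is applied as a
## relative bound: |angle - 90| <= tol * 90 for right angles, pairwise
## differences <= tol * pair mean for equalities, and undirected direction
## differences <= tol * 90 degrees for parallelism. All predicates are
## invariant under translation, rotation and uniform scaling and reduce to
## exact predicates as the tolerance goes to 0.

.pair_idx <- utils::combn(4, 2)   # pair order: 12 13 14 23 24 34

#' Interior angles of a simple quadrilateral
#'
#' @param q `quad` object or 4x2 vertex matrix (counterclockwise).
#' @return numeric vector of 4 angles in degrees, one per vertex; they sum
#'   to 360. Reflex (concave) vertices yield angles above 180.
#' @export
interior_angles <- function(q) {
  v <- if (inherits(q, "quad")) q$vertices else q
  if (.polygon_area2(v) < 0) v <- v[4:1, , drop = FALSE]
  ang <- numeric(4)
  for (i in 1:4) {
    a <- v[(i - 2) %% 4 + 1, ] - v[i, ]
    b <- v[i %% 4 + 1, ] - v[i, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) stop("degenerate quadrilateral: coincident vertices")
    raw <- acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
    ## convexity at vertex i (counterclockwise orientation)
    cr <- (v[i, 1] - v[(i - 2) %% 4 + 1, 1]) * (v[i %% 4 + 1, 2] - v[i, 2]) -
          (v[i, 2] - v[(i - 2) %% 4 + 1, 2]) * (v[i %% 4 + 1, 1] - v[i, 1])
    ang[i] <- if (cr >= 0) raw else 360 - raw
  }
  if (abs(sum(ang) - 360) > 1e-6)
    stop("interior angles do not sum to 360 degrees; polygon may be degenerate")
  ang
}

#' Extract the 22 binary geometric features of a quadrilateral
#'
#' @param q `quad` object or 4x2 vertex matrix.
#' @param tolerance relative tolerance in (0, 1); default 0.125.
#' @return a `feature_vector`: named logical vector of length 22 with a
#'   `tolerance` attribute. Names encode the predicate, e.g. `right_angle_2`,
#'   `equal_angles_1_3`, `equal_sides_2_4`, `parallel_sides_1_3` (sides are
#'   numbered by their starting vertex).
#' @export
feature_vector <- function(q, tolerance = 0.125) {
  stopifnot(is.numeric(tolerance), tolerance > 0, tolerance < 1)
  v <- if (inherits(q, "quad")) q$vertices else q
  if (!is_simple_quad(v)) stop("feature extraction requires a simple polygon")
  ang <- interior_angles(v)
  edges <- v[c(2, 3, 4, 1), ] - v
  len <- sqrt(rowSums(edges^2))
  dir <- atan2(edges[, 2], edges[, 1]) * 180 / pi  # undirected, mod 180

  right <- abs(ang - 90) <= tolerance * 90
  i <- .pair_idx[1, ]; j <- .pair_idx[2, ]
  eq_ang <- abs(ang[i] - ang[j]) <= tolerance * (ang[i] + ang[j]) / 2
  eq_side <- abs(len[i] - len[j]) <= tolerance * (len[i] + len[j]) / 2
  dd <- abs(dir[i] - dir[j]) %% 180
  dd <- pmin(dd, 180 - dd)
  par_side <- dd <= tolerance * 90

  out <- c(right, eq_ang, eq_side, par_side)
  pair_nm <- paste(i, j, sep = "_")
  names(out) <- c(paste0("right_angle_", 1:4),
                  paste0("equal_angles_", pair_nm),
                  paste0("equal_sides_", pair_nm),
                  paste0("parallel_sides_", pair_nm))
  structure(out, tolerance = tolerance, class = c("feature_vector", "logical"))
}

#' Regularity score: number of geometric features possessed
#' @param fv a `feature_vector` (or any logical vector).
#' @return integer count in 0..22.
#' @export
regularity_score <- function(fv) sum(fv)

#' Dissimilarity between two feature vectors
#'
#' The default (`method = "hamming"`) counts the features not in common
#' (symmetric difference of the two feature sets), a metric on feature
#' vectors. `method = "count"` is an alternative reading that compares only
#' the total number of features; it coincides with Hamming when the feature
#' sets are nested.
#'
#' @param a,b `feature_vector`s extracted at the same tolerance.
#' @param method `"hamming"` (default) or `"count"`.
#' @return non-negative integer.
#' @export
feature_dissimilarity <- function(a, b, method = c("hamming", "count")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("feature vectors differ in length")
  ta <- attr(a, "tolerance"); tb <- attr(b, "tolerance")
  if (!is.null(ta) && !is.null(tb) && abs(ta - tb) > 1e-12)
    stop("feature vectors were extracted at different tolerances")
  if (method == "hamming") sum(xor(a, b)) else abs(sum(a) - sum(b))
}

#' Feature-model RDM over a set of shapes
#'
#' @param shapes named list of `quad` objects (names become condition labels).
#' @param tolerance feature tolerance.
#' @param method dissimilarity method, see [feature_dissimilarity()].
#' @return an [rdm] with metric `"hamming-features"` (or `"count-features"`).
#' @export
feature_rdm <- function(shapes, tolerance = 0.125,
                        method = c("hamming", "count")) {
  method <- match.arg(method)
  if (length(shapes) < 2) stop("need at least 2 shapes")
  labels <- names(shapes)
  if (is.null(labels) || anyDuplicated(labels))
    stop("shapes must be uniquely named")
  fvs <- lapply(shapes, feature_vector, tolerance = tolerance)
  n <- length(fvs)
  pr <- utils::combn(n, 2)
  vals <- apply(pr, 2, function(p)
    feature_dissimilarity(fvs[[p[1]]], fvs[[p[2]]], method = method))
  rdm(vals, labels, metric = paste0(method, "-features"))
}

#' Feature table for a set of shapes
#'
#' @param shapes named list of `quad`s.
#' @param tolerance feature tolerance.
#' @return data.frame: one row per shape, 22 logical feature columns plus
#'   `score`.
#' @export
feature_table <- function(shapes, tolerance = 0.125) {
  fvs <- lapply(shapes, feature_vector, tolerance = tolerance)
  tab <- as.data.frame(do.call(rbind, lapply(fvs, as.logical)))
  names(tab) <- names(fvs[[1]])
  tab$score <- vapply(fvs, regularity_score, integer(1))
  cbind(shape = names(shapes), tab)
}
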