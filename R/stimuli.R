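## Quadrilateral stimuli -------------------------------------------------
##
## The stimulus set consists of 11 quadrilaterals graded in geometric
## regularity, from the square down to a fully irregular shape. All shapes
## are matched on the mean pairwise distance between their four vertices
## (mpd), the quantity used to standardize deviant displacements. Where the
## family geometry permits it, the bottom side is additionally pinned to a
## common length; for the parallelogram-like families (rectangle,
## parallelogram, losange) both constraints cannot hold jointly (among
## parallelograms with a fixed bottom side, the square uniquely maximizes
## mpd), so there the proportions are fixed and a uniform scale enforces the
## mpd match, with the residual bottom-side deviation recorded.

#' The 11 reference shape family names, from most to least regular
#' @export
shape_families <- function() {
  c("square", "rectangle", "losange", "parallelogram", "isoTrapezoid",
    "rightKite", "kite", "rightHinge", "hinge", "trapezoid", "random")
}

#' Scale / rotation sampling sets used by the different experiments
#'
#' `online`: ten values per dimension, used in the web-based visual search
#' task; `lab`: six values per dimension, used for the intruder displays and
#' the MEG miniblocks. Rotation sets exclude 0 degrees so that sides are
#' never exactly vertical or horizontal.
#' @param which `"online"` or `"lab"`.
#' @return list with elements `scales` and `rotations` (degrees).
#' @export
transform_sets <- function(which = c("online", "lab")) {
  which <- match.arg(which)
  if (which == "online") {
    list(scales = c(0.85, 0.88, 0.92, 0.95, 0.98, 1.02, 1.05, 1.08, 1.12, 1.15),
         rotations = c(-25, -19.4, -13.8, -8.3, -2.7, 2.7, 8.3, 13.8, 19.4, 25))
  } else {
    list(scales = c(0.875, 0.925, 0.975, 1.025, 1.075, 1.125),
         rotations = c(-25, -15, -5, 5, 15, 25))
  }
}

## mean pairwise distance between the 4 vertices (6 pairs)
#' Mean pairwise vertex distance of a quadrilateral
#' @param q a `quad` object or a 4x2 vertex matrix.
#' @return positive scalar.
#' @export
mpd <- function(q) {
  v <- if (inherits(q, "quad")) q$vertices else q
  mean(stats::dist(v))
}

.polygon_area2 <- function(v) {
  ## twice the signed area (positive for counterclockwise vertices)
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(2:4, 1)
  sum(x * y[i2] - x[i2] * y)
}

## segment intersection test used for polygon simplicity; proper crossing or
## improper touch both count as an intersection
.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (abs(d1) < 1e-12 && on_seg(p3, p4, p1)) || (abs(d2) < 1e-12 && on_seg(p3, p4, p2)) ||
  (abs(d3) < 1e-12 && on_seg(p1, p2, p3)) || (abs(d4) < 1e-12 && on_seg(p1, p2, p4))
}

#' Is a quadrilateral a simple (non self-intersecting) polygon?
#' @param q a `quad` object or 4x2 vertex matrix.
#' @return logical.
#' @export
is_simple_quad <- function(q) {
  v <- if (inherits(q, "quad")) q$vertices else q
  ## only the two pairs of opposite (non-adjacent) edges can cross
  e <- list(v[c(1, 2), ], v[c(2, 3), ], v[c(3, 4), ], v[c(4, 1), ])
  !(.segments_intersect(e[[1]][1, ], e[[1]][2, ], e[[3]][1, ], e[[3]][2, ]) ||
    .segments_intersect(e[[2]][1, ], e[[2]][2, ], e[[4]][1, ], e[[4]][2, ]))
}

.quad <- function(vertices, family, scale = 1, rotation_deg = 0,
                  bottom_target = NA_real_) {
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(
    list(vertices = vertices, family = family, scale = scale,
         rotation_deg = rotation_deg,
         bottom_side = sqrt(sum((vertices[2, ] - vertices[1, ])^2)),
         bottom_target = bottom_target),
    class = "quad")
}

#' @export
print.quad <- function(x, ...) {
  cat(sprintf("<quad '%s'> bottom side %.4f, mpd %.4f, scale %.3g, rotation %.3g deg\n",
              x$family, x$bottom_side, mpd(x), x$scale, x$rotation_deg))
  invisible(x)
}

## translate the vertex centroid to the origin
.center_quad <- function(v) sweep(v, 2, colMeans(v))

## Family catalogue. Each entry builds canonical-pose vertices (vertex 1 =
## bottom-left, vertex 2 = bottom-right, counterclockwise; bottom side along
## the x axis with unit length) as a function of one free parameter. mode
## "param" solves the parameter so mpd matches the square's; mode "scale"
## keeps fixed proportions and rescales uniformly (bottom side deviates).
.family_defs <- function() {
  deg <- pi / 180
  list(
    square = list(
      mode = "fixed",
      f = function(p) rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
    rectangle = list(
      mode = "scale",                      # aspect 1:1.7, taller than wide
      f = function(p) rbind(c(0, 0), c(1, 0), c(1, 1.7), c(0, 1.7))),
    losange = list(
      mode = "scale",                      # rhombus, 60 degree base angle
      f = function(p) {
        c60 <- cos(60 * deg); s60 <- sin(60 * deg)
        rbind(c(0, 0), c(1, 0), c(1 + c60, s60), c(c60, s60))
      }),
    parallelogram = list(
      mode = "scale",                      # 60 degree skew, side ratio 0.7
      f = function(p) {
        c60 <- cos(60 * deg); s60 <- sin(60 * deg)
        rbind(c(0, 0), c(1, 0), c(1 + 0.7 * c60, 0.7 * s60), c(0.7 * c60, 0.7 * s60))
      }),
    isoTrapezoid = list(
      mode = "param", range = c(0.2, 4),   # top/bottom ratio 0.3, solve height
      f = function(h) rbind(c(0, 0), c(1, 0), c(0.65, h), c(0.35, h))),
    rightKite = list(
      mode = "scale",                      # right angles flanking the axis;
      f = function(p) {                    # side ratio 1.75, fixed proportions
        b <- 1.75
        ## v1=(0,0), v2=(1,0), v4=(0,b); right angles at v1 and v3 (cyclic,
        ## diameter v2-v4); v3 mirrors v1 across the axis v2->v4
        a <- c(0, b)                        # v4
        u <- (a - c(1, 0)) / sqrt(1 + b^2)  # unit axis from v2 to v4
        p1 <- c(-1, 0)                      # v1 relative to v2
        refl <- 2 * sum(p1 * u) * u - p1    # reflect v1 about the axis
        rbind(c(0, 0), c(1, 0), c(1, 0) + refl, a)
      }),
    kite = list(
      mode = "scale",                      # apex 145 deg at vertex 2, short
      f = function(p) {                    # and long side pair ratio 1:1.2
        phi <- 145 * deg; b <- 1.2
        v3 <- c(1 - cos(phi), sin(phi))    # |v2-v3| = 1
        ax <- c(cos(pi - phi / 2), sin(pi - phi / 2))
        v3rel <- v3 - c(1, 0)
        Bq <- -2 * sum(ax * v3rel); Cq <- sum(v3rel^2) - b^2
        r <- (-Bq + sqrt(Bq^2 - 4 * Cq)) / 2  # |v4-v3| = b, v4 on the axis
        rbind(c(0, 0), c(1, 0), v3, c(1, 0) + r * ax)
      }),
    rightHinge = list(
      mode = "param", range = c(0.3, 4),   # equal sides at a right angle
      f = function(t) rbind(c(0, 0), c(1, 0), c(1, 1), c(0.65, t))),
    hinge = list(
      mode = "param", range = c(0.2, 4),   # equal sides at a 128 deg angle
      f = function(t) {
        v3 <- c(1 + cos(52 * deg), sin(52 * deg))
        rbind(c(0, 0), c(1, 0), v3, c(0, t))
      }),
    trapezoid = list(
      mode = "param", range = c(0.05, 3),  # one parallel pair, legs flare out
      f = function(h) {
        rbind(c(0, 0), c(1, 0),
              c(1 + h / tan(75 * deg), h), c(-h / tan(55 * deg), h))
      }),
    random = list(
      mode = "param", range = c(0.25, 3),  # frozen irregular proportions with
      f = function(t)                      # zero features at tolerance 0.125
        rbind(c(0, 0), c(1, 0), c(1.3973, 0.3227 * t), c(-0.2641, 1.5605 * t)))
  )
}

#' Construct the 11 regularity-graded reference quadrilaterals
#'
#' All families are matched exactly (relative tolerance 1e-9) on the mean
#' pairwise vertex distance of a square with side `bottom_side_length`.
#' Families with a free shape parameter additionally keep their bottom side
#' at `bottom_side_length`; for the rectangle, losange and parallelogram the
#' two constraints are jointly infeasible, so fixed proportions are scaled
#' uniformly and the achieved bottom side is reported in the returned object.
#'
#' Shapes are in canonical pose: bottom side (edge between vertices 1 and 2)
#' horizontal, vertices counterclockwise, centroid at the origin.
#'
#' @param bottom_side_length positive scalar, length of the square's side.
#' @return named list of `quad` objects, one per family.
#' @export
make_reference_shapes <- function(bottom_side_length = 1) {
  stopifnot(is.numeric(bottom_side_length), bottom_side_length > 0)
  L <- bottom_side_length
  target <- (2 + sqrt(2)) / 3          # mpd of the unit square
  defs <- .family_defs()
  out <- vector("list", length(defs))
  names(out) <- names(defs)
  for (fam in names(defs)) {
    def <- defs[[fam]]
    v <- switch(def$mode,
      fixed = def$f(NULL),
      scale = {
        v0 <- def$f(NULL)
        v0 * (target / mpd(v0))
      },
      param = {
        g <- function(p) mpd(def$f(p)) - target
        sol <- tryCatch(
          stats::uniroot(g, interval = def$range, tol = .Machine$double.eps^0.8),
          error = function(e) stop(sprintf(
            "constraint solver failed for family '%s': %s", fam, conditionMessage(e)),
            call. = FALSE))
        def$f(sol$root)
      })
    v <- .center_quad(v * L)
    if (.polygon_area2(v) < 0) v <- v[c(2, 1, 4, 3), , drop = FALSE]
    q <- .quad(v, fam, bottom_target = L)
    if (!is_simple_quad(q))
      stop(sprintf("family '%s' produced a self-intersecting polygon", fam))
    out[[fam]] <- q
  }
  out
}

#' Similarity-transform a quadrilateral about its centroid
#'
#' @param q `quad` object.
#' @param scale positive scale factor.
#' @param rotation_deg rotation in degrees (counterclockwise).
#' @return transformed `quad`; mean pairwise distance scales by `scale`.
#' @export
transform_shape <- function(q, scale = 1, rotation_deg = 0) {
  stopifnot(inherits(q, "quad"))
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  ctr <- colMeans(q$vertices)
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v <- sweep(q$vertices, 2, ctr)
  v <- scale * (v %*% t(R))
  v <- sweep(v, 2, ctr, `+`)
  q2 <- .quad(v, q$family, scale = q$scale * scale,
              rotation_deg = q$rotation_deg + rotation_deg,
              bottom_target = q$bottom_target)
  q2
}

#' Sample scale/rotation pairs without replacement
#'
#' Draws `n` scales and `n` rotations without replacement from the supplied
#' sets and pairs them in random order, as done when composing a display of
#' several exemplars of the same shape.
#'
#' @param n number of pairs; must not exceed either set size.
#' @param scale_set,rotation_set candidate values; the rotation set must not
#'   contain 0 degrees (sides must never be exactly axis-aligned).
#' @param seed integer seed (RNG state is restored on exit).
#' @return data.frame with columns `scale` and `rotation`.
#' @export
sample_transforms <- function(n, scale_set = transform_sets("online")$scales,
                              rotation_set = transform_sets("online")$rotations,
                              seed = NULL) {
  if (n > length(scale_set) || n > length(rotation_set))
    stop("n exceeds the size of a sampling set")
  if (any(rotation_set == 0))
    stop("rotation_set must not contain 0 degrees")
  with_seed(seed, {
    data.frame(scale = sample(scale_set, n),
               rotation = sample(rotation_set, n))
  })
}

#' Displace the bottom-right corner to create a deviant shape
#'
#' The bottom-right vertex (index 2 in canonical pose) is moved by
#' `magnitude_fraction` times the shape's mean pairwise vertex distance, in
#' one of four diagonal directions (45, 135, 225, 315 degrees from the
#' canonical x axis). The other three vertices are untouched.
#'
#' @param q `quad` in canonical pose (rotation 0).
#' @param magnitude_fraction displacement as a fraction of mpd; default 0.45.
#' @param direction integer in 1..4 selecting the displacement direction.
#' @return deviant `quad` (same family, `deviant` attribute set). Errors if
#'   the displaced polygon self-intersects.
#' @export
make_deviant <- function(q, magnitude_fraction = 0.45, direction = 1L) {
  stopifnot(inherits(q, "quad"))
  if (!is.numeric(magnitude_fraction) || magnitude_fraction < 0)
    stop("magnitude_fraction must be non-negative")
  if (!direction %in% 1:4) stop("direction must be in 1..4")
  if (abs(q$rotation_deg) > 1e-9)
    stop("make_deviant expects a shape in canonical pose (rotation 0)")
  ang <- c(45, 135, 225, 315)[direction] * pi / 180
  u <- c(cos(ang), sin(ang))
  v <- q$vertices
  v[2, ] <- v[2, ] + magnitude_fraction * mpd(q) * u
  if (!is_simple_quad(v))
    stop(sprintf("direction %d yields a self-intersecting polygon for '%s'",
                 direction, q$family))
  q2 <- .quad(v, q$family, scale = q$scale, rotation_deg = q$rotation_deg,
              bottom_target = q$bottom_target)
  attr(q2, "deviant") <- list(magnitude_fraction = magnitude_fraction,
                              direction = as.integer(direction))
  q2
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not perturb
#' the caller's RNG stream. With `seed = NULL` the expression runs on the
#' current stream.
#' @param seed integer or NULL.
#' @param expr expression to evaluate.
#' @keywords internal
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
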