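test_that("the 11 reference shapes are matched on mean pairwise distance", {
  sh <- shapes11()
  expect_named(sh, shape_families(), ignore.order = TRUE)
  L <- 1
  target <- (2 + sqrt(2)) / 3   # closed form for the unit square
  expect_equal(mpd(sh$square), target, tolerance = 1e-12)
  mpds <- vapply(sh, mpd, numeric(1))
  expect_lt(max(abs(mpds - target)) / target, 1e-6)
  ## families with a free parameter keep the bottom side exactly
  for (f in c("square", "isoTrapezoid", "hinge", "rightHinge", "trapezoid",
              "random"))
    expect_equal(sh[[f]]$bottom_side, L, tolerance = 1e-9,
                 label = paste("bottom side of", f))
  ## every shape is a simple polygon (checked against the exhaustive oracle)
  for (f in names(sh)) {
    expect_true(is_simple_quad(sh[[f]]), label = paste(f, "simple"))
    expect_true(oracle_is_simple(sh[[f]]$vertices), label = paste(f, "oracle"))
  }
  ## scaling the bottom side scales everything
  sh2 <- make_reference_shapes(2.5)
  expect_equal(mpd(sh2$square), 2.5 * target, tolerance = 1e-12)
  expect_equal(sh2$trapezoid$vertices, 2.5 * sh$trapezoid$vertices,
               tolerance = 1e-9)
})

test_that("constrained construction agrees with an independent bisection oracle", {
  defs <- geomrep:::.family_defs()
  target <- (2 + sqrt(2)) / 3
  bisect <- function(g, lo, hi, iters = 200) {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  sh <- shapes11()
  for (fam in c("isoTrapezoid", "trapezoid", "hinge", "random")) {
    def <- defs[[fam]]
    g <- function(p) mpd(def$f(p)) - target
    root <- bisect(g, def$range[1], def$range[2])
    expect_equal(mpd(def$f(root)), target, tolerance = 1e-9,
                 label = paste(fam, "bisection root"))
    expect_equal(mpd(sh[[fam]]), mpd(def$f(root)), tolerance = 1e-9,
                 label = paste(fam, "solver vs oracle"))
  }
})

test_that("similarity transforms behave as similarity transforms", {
  q <- shapes11()$square
  expect_equal(transform_shape(q, 1, 0)$vertices, q$vertices)
  expect_equal(mpd(transform_shape(q, 2, 0)), 2 * mpd(q), tolerance = 1e-12)
  ## rotation then inverse rotation is the identity
  q2 <- transform_shape(transform_shape(q, 1, 25), 1, -25)
  expect_equal(q2$vertices, q$vertices, tolerance = 1e-12)
  ## mpd is rotation invariant
  expect_equal(mpd(transform_shape(q, 1, 73.2)), mpd(q), tolerance = 1e-12)
  expect_error(transform_shape(q, -1), "positive")
})

test_that("transform sampling is without replacement, seeded, and rejects 0 deg", {
  sets <- transform_sets("online")
  expect_length(sets$scales, 10)
  expect_length(sets$rotations, 10)
  s1 <- sample_transforms(9, sets$scales, sets$rotations, seed = 4)
  expect_equal(nrow(s1), 9)
  expect_false(any(duplicated(s1$scale)))
  expect_false(any(duplicated(s1$rotation)))
  expect_identical(s1, sample_transforms(9, sets$scales, sets$rotations, seed = 4))
  ## n = full lab set size gives a permutation of each set
  lab <- transform_sets("lab")
  s2 <- sample_transforms(6, lab$scales, lab$rotations, seed = 1)
  expect_setequal(s2$scale, lab$scales)
  expect_setequal(s2$rotation, lab$rotations)
  expect_error(sample_transforms(11, sets$scales, sets$rotations), "exceeds")
  expect_error(sample_transforms(3, 1:5, c(-1, 0, 1, 2)), "0 degrees")
})

test_that("deviants displace one corner by the standardized fraction", {
  sh <- shapes11()
  for (fam in c("square", "losange", "random")) {
    q <- sh[[fam]]
    n_ok <- 0
    for (d in 1:4) {
      ## directions that break simplicity are rejected with an explicit
      ## error; the caller may try another direction
      dv <- tryCatch(make_deviant(q, 0.45, d), error = function(e) {
        expect_match(conditionMessage(e), "self-intersecting")
        NULL
      })
      if (is.null(dv)) next
      n_ok <- n_ok + 1
      moved <- sqrt(sum((dv$vertices[2, ] - q$vertices[2, ])^2))
      expect_equal(moved, 0.45 * mpd(q), tolerance = 1e-12)
      expect_equal(dv$vertices[-2, ], q$vertices[-2, ])
      expect_true(oracle_is_simple(dv$vertices))
    }
    expect_gte(n_ok, 2)
  }
  ## four directions give four distinct simple quadrilaterals
  devs <- lapply(1:4, function(d) make_deviant(sh$square, 0.45, d)$vertices)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(max(abs(devs[[i]] - devs[[j]])), 0.1)
  ## zero-magnitude limit returns the input
  expect_equal(make_deviant(sh$square, 0)$vertices, sh$square$vertices)
  ## deviants of the square lose regularities
  expect_lt(regularity_score(feature_vector(make_deviant(sh$square, 0.45, 2))),
            regularity_score(feature_vector(sh$square)))
  expect_error(make_deviant(transform_shape(sh$square, 1, 10)), "canonical")
})
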