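test_that("pooled empirical RDM matches a hand computation on a toy set", {
  tr <- toy_trials()
  r <- empirical_rdm(tr, zscore = FALSE)
  expect_identical(r$labels, c("a", "b", "c"))
  expect_equal(r$values, toy_expected_raw(), tolerance = 1e-12)
  ## z-scored version has mean 0 / sd 1 over the off-diagonal entries
  rz <- empirical_rdm(tr)
  expect_equal(mean(rz$values), 0, tolerance = 1e-12)
  expect_equal(sd(rz$values), 1, tolerance = 1e-12)
  ## raw values preserved alongside
  expect_equal(rz$raw_values, r$values, tolerance = 1e-12)
  ## a single pair: accuracy 0.9 / mean RT 1500 -> 6e-4 per ms
  tr2 <- data.frame(participant = 1, reference = rep(c("x", "y"), each = 10),
                    intruder = rep(c("y", "x"), each = 10),
                    correct = rep(c(rep(TRUE, 9), FALSE), 2), rt = 1500)
  r2 <- empirical_rdm(tr2, zscore = FALSE)
  expect_equal(r2$values, 0.9 / 1500, tolerance = 1e-12)
})

test_that("empirical RDM symmetrizes ordered estimates and ignores trial order", {
  ## ordered estimates 2u and 4u average to 3u
  tr <- data.frame(participant = 1,
                   reference = c("a", "b"), intruder = c("b", "a"),
                   correct = c(TRUE, TRUE), rt = c(500, 250))
  r <- empirical_rdm(tr, zscore = FALSE)
  expect_equal(r$values, mean(c(1 / 500, 1 / 250)), tolerance = 1e-12)
  ## permutation of rows and participant relabeling change nothing
  tr3 <- toy_trials()
  set.seed(20)
  perm <- sample(nrow(tr3))
  tr3b <- tr3[perm, ]
  tr3b$participant <- rep(99, nrow(tr3b))   # pooled: labels irrelevant
  expect_equal(empirical_rdm(tr3b)$values, empirical_rdm(tr3)$values)
  ## per-participant mode returns raw single-trial cells (0 or 1/RT)
  rl <- empirical_rdm(toy_trials(), pool = FALSE)
  expect_length(rl, 2)
  expect_true(all(vapply(rl, function(x) all(x$values >= 0), logical(1))))
  ## empty cell errors
  expect_error(empirical_rdm(toy_trials()[1:3, ]), "no trials")
})

test_that("RDM regression recovers exact and noisy coefficients", {
  set.seed(21)
  labs <- paste0("c", 1:11)
  m1 <- rdm(rnorm(55), labs); m2 <- rdm(rnorm(55), labs)
  ## empirical identical to model 1
  r <- rdm_regression(rdm(m1$values, labs), list(m1 = m1, m2 = m2),
                      standardize = FALSE)
  expect_equal(unname(r$coefficients), c(1, 0), tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  ## exact linear combination
  y <- rdm(2 * m1$values + 1 * m2$values + 5, labs)
  r2 <- rdm_regression(y, list(m1 = m1, m2 = m2), standardize = FALSE)
  expect_equal(unname(r2$coefficients), c(2, 1), tolerance = 1e-10)
  ## noisy case equals the normal-equations oracle
  yv <- 1.5 * m1$values - 0.8 * m2$values + rnorm(55)
  X <- cbind(1, m1$values, m2$values)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  r3 <- rdm_regression(rdm(yv, labs), list(m1 = m1, m2 = m2),
                       standardize = FALSE)
  expect_equal(unname(r3$coefficients), drop(beta)[2:3], tolerance = 1e-10)
  ## single-model regression equals cov/var slope
  r4 <- rdm_regression(rdm(yv, labs), list(m1 = m1), standardize = FALSE)
  expect_equal(unname(r4$coefficients),
               cov(yv, m1$values) / var(m1$values), tolerance = 1e-10)
  ## rank-deficient design errors
  expect_error(rdm_regression(rdm(yv, labs), list(a = m1, b = m1)),
               "rank-deficient")
})

test_that("label subsetting supports the named-shape exclusion reanalysis", {
  sh <- shapes11()
  fr <- feature_rdm(sh)
  keep <- setdiff(fr$labels, c("square", "rectangle", "isoTrapezoid",
                               "trapezoid", "losange", "parallelogram"))
  sub <- subset_rdm(fr, keep)
  expect_length(sub$labels, 5)
  expect_length(sub$values, 10)
  m_full <- as.matrix(fr); m_sub <- as.matrix(sub)
  expect_equal(m_sub, m_full[keep, keep])
})

test_that("ordinal MDS recovers planar configurations and is deterministic", {
  set.seed(22)
  pts <- matrix(rnorm(22), 11, 2)
  d <- as.matrix(dist(pts))
  r <- rdm_from_matrix(d, paste0("c", 1:11))
  emb <- mds_embed(r, seed = 7)
  expect_lt(emb$stress, 1e-3)
  ## ordinal MDS preserves ranks, so metric recovery is approximate
  aligned <- procrustes_align(pts, emb$points)
  expect_lt(sqrt(mean((aligned - pts)^2)) / sd(pts), 0.05)
  ## determinism
  emb2 <- mds_embed(r, seed = 7)
  expect_identical(emb$points, emb2$points)
  ## three equidistant points embed as an equilateral triangle
  r3 <- rdm(c(1, 1, 1), c("a", "b", "c"))
  e3 <- mds_embed(r3, seed = 1)
  side <- dist(e3$points)
  expect_lt(diff(range(side)) / mean(side), 0.01)
  expect_error(mds_embed(rdm(1, c("a", "b")), k = 2), "k\\+1")
})

test_that("property projection works and constant properties error", {
  set.seed(23)
  coords <- matrix(rnorm(22), 11, 2)
  p <- project_property(coords, coords[, 1])
  expect_equal(unname(p$coefficients), c(1, 0), tolerance = 1e-10)
  expect_error(project_property(coords, rep(2, 11)), "zero variance")
})

test_that("bootstrap projection finds a planted property direction", {
  ## trials generated from the feature model; the regularity score should
  ## project onto the embedding with a significant coefficient
  sh <- shapes11()
  fr <- feature_rdm(sh)
  trials <- simulate_behavior(fr, n_participants = 60, seed = 31)
  prop <- feature_table(sh)$score[match(sort(names(sh)), names(sh))]
  bp <- bootstrap_projection(trials, prop, n_boot = 60, seed = 5,
                             mds_restarts = 2)
  expect_lt(min(bp$p), 0.05)
  expect_equal(dim(bp$boot_coefficients), c(60L, 2L))
})

test_that("per-participant regression compares model weights", {
  set.seed(24)
  labs <- paste0("c", 1:11)
  m1 <- rdm(rnorm(55), labs); m2 <- rdm(rnorm(55), labs)
  ## every participant weights model 1 about 3x more than model 2
  units <- lapply(1:15, function(i)
    rdm(3 * scale(m1$values)[, 1] + 1 * scale(m2$values)[, 1] +
        rnorm(55, sd = 0.1), labs))
  pooled <- rdm(rowMeans(sapply(units, `[[`, "values")), labs)
  r <- rdm_regression(pooled, list(m1 = m1, m2 = m2), per_unit = units)
  expect_equal(dim(r$unit_coefficients), c(15L, 2L))
  expect_gt(r$weight_ratio, 2)
  expect_lt(r$weight_ratio, 4)
  expect_lt(r$comparison$p.value, 0.001)
})
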