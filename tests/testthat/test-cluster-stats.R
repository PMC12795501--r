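test_that("temporal cluster test matches exhaustive sign enumeration on a toy array", {
  set.seed(30)
  x <- matrix(rnorm(30), 3, 10) + 1.5
  ours <- temporal_cluster_test(x, exact = TRUE)
  oracle <- oracle_temporal_clusters(x)
  expect_equal(sort(ours$clusters$mass), sort(oracle$obs), tolerance = 1e-10)
  expect_equal(sort(ours$perm_max), sort(oracle$perm_max), tolerance = 1e-10)
  expect_equal(ours$clusters$p[order(ours$clusters$mass)],
               oracle$p[order(oracle$obs)], tolerance = 1e-12)
})

test_that("strong constant effects give one full-span cluster at the minimal p", {
  set.seed(31)
  x <- matrix(rnorm(20 * 40, mean = 3), 20, 40)
  ct <- temporal_cluster_test(x, n_perm = 512, seed = 2)
  expect_equal(nrow(ct$clusters), 1)
  expect_equal(ct$clusters$start, 1)
  expect_equal(ct$clusters$end, 40)
  expect_equal(ct$clusters$p, 0)   # k/N convention: no observed re-adding
  ## p is monotone non-increasing in mass
  pm <- ct$perm_max
  masses <- sort(runif(10, 0, max(pm) * 1.2))
  ps <- vapply(masses, permutation_p, numeric(1), perm_max = pm)
  expect_true(all(diff(ps) <= 0))
})

test_that("zero-variance timepoints are excluded, determinism holds", {
  set.seed(32)
  x <- matrix(rnorm(10 * 20, mean = 2), 10, 20)
  x[, 5] <- 1   # zero variance
  ct <- temporal_cluster_test(x, n_perm = 256, seed = 9)
  expect_true(is.na(ct$t[5]))
  expect_false(any(ct$clusters$start <= 5 & ct$clusters$end >= 5))
  ct2 <- temporal_cluster_test(x, n_perm = 256, seed = 9)
  expect_identical(ct$clusters, ct2$clusters)
  expect_error(temporal_cluster_test(x[1, , drop = FALSE]), "participants")
})

test_that("the volumetric sign-swap test reproduces the worked p-value arithmetic", {
  ## a cluster whose mass is outperformed by 3 of 10,000 swaps has p 0.0003
  perm_max <- c(rep(0.5, 9997), 10, 11, 12)
  expect_equal(permutation_p(9, perm_max), 0.0003)
  expect_equal(permutation_p(13, perm_max), 0)
})

test_that("spatial clusters respect adjacency and recover a planted blob", {
  ## two supra-threshold voxels two apart under 6-connectivity: two clusters
  set.seed(33)
  dims <- c(8, 8, 8)
  base <- lapply(1:8, function(i) array(rnorm(prod(dims), sd = 0.1), dims))
  for (i in seq_along(base)) {
    base[[i]][2, 2, 2] <- 5 + rnorm(1, sd = 0.1)
    base[[i]][2, 2, 4] <- 5 + rnorm(1, sd = 0.1)
  }
  ct <- spatial_cluster_test(base, alpha = 0.001, n_perm = 200, seed = 1)
  lin <- function(x, y, z) (z - 1) * 64 + (y - 1) * 8 + x
  holds1 <- vapply(ct$clusters$voxels, function(v) lin(2, 2, 2) %in% v, logical(1))
  holds2 <- vapply(ct$clusters$voxels, function(v) lin(2, 2, 4) %in% v, logical(1))
  expect_equal(sum(holds1), 1); expect_equal(sum(holds2), 1)
  expect_false(which(holds1) == which(holds2))  # two voxels apart: 2 clusters
  ## an added bridging voxel merges them into one cluster
  for (i in seq_along(base)) base[[i]][2, 2, 3] <- 5 + rnorm(1, sd = 0.1)
  ct2 <- spatial_cluster_test(base, alpha = 0.001, n_perm = 200, seed = 1)
  holds <- vapply(ct2$clusters$voxels, function(v)
    all(lin(2, 2, 2:4) %in% v), logical(1))
  expect_equal(sum(holds), 1)

  ## planted 5^3 blob in a 20^3 grid at high SNR: recovered with Jaccard >= 0.5
  dims <- c(20, 20, 20)
  blob <- array(FALSE, dims); blob[8:12, 8:12, 8:12] <- TRUE
  maps <- lapply(1:10, function(i) {
    m <- array(rnorm(prod(dims)), dims)
    m[blob] <- m[blob] + 3
    m
  })
  ct3 <- spatial_cluster_test(maps, alpha = 0.001, n_perm = 300, seed = 2)
  sig <- ct3$clusters[ct3$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  vox <- sig$voxels[[which.max(sig$size)]]
  jac <- length(intersect(vox, which(blob))) / length(union(vox, which(blob)))
  expect_gte(jac, 0.5)
})

test_that("two-sided and negative-tail variants detect signed effects", {
  set.seed(34)
  x <- matrix(rnorm(15 * 60), 15, 60)
  x[, 10:20] <- x[, 10:20] - 1.5    # negative effect
  ## one-tailed positive test must not flag it, two-sided and "less" must
  ct_pos <- temporal_cluster_test(x, n_perm = 512, seed = 1, tail = "greater")
  expect_false(any(ct_pos$clusters$p < 0.05 & ct_pos$clusters$sign > 0 &
                   ct_pos$clusters$start <= 20 & ct_pos$clusters$end >= 10))
  ct_two <- temporal_cluster_test(x, n_perm = 512, seed = 1, tail = "two.sided")
  hit <- ct_two$clusters$p < 0.05 & ct_two$clusters$sign < 0
  expect_true(any(hit & ct_two$clusters$start <= 12 & ct_two$clusters$end >= 18))
  ct_neg <- temporal_cluster_test(x, n_perm = 512, seed = 1, tail = "less")
  expect_true(any(ct_neg$clusters$p < 0.05))
  ## spatial two-sided finds a planted negative blob
  dims <- c(10, 10, 10)
  maps <- lapply(1:10, function(i) {
    m <- array(rnorm(prod(dims)), dims); m[4:6, 4:6, 4:6] <- m[4:6, 4:6, 4:6] - 3; m
  })
  ct_sp <- spatial_cluster_test(maps, alpha = 0.001, n_perm = 300, seed = 2,
                                tail = "two.sided")
  sig <- ct_sp$clusters[ct_sp$clusters$p < 0.05 & ct_sp$clusters$sign < 0, ]
  expect_gte(nrow(sig), 1)
})
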