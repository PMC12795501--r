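## small synthetic epoch sets keep the decoding unit tests fast
tiny_epochs <- function(n_runs = 8, n_block = 10, n_channels = 6, nt = 12,
                        shapes = c("s1", "s2"), shift = 0, seed = 1,
                        oddball_window = NULL) {
  set.seed(seed)
  n_ep <- n_runs * n_block * length(shapes)
  info <- expand.grid(pos = seq_len(n_block), shape = shapes,
                      run = seq_len(n_runs), stringsAsFactors = FALSE)
  info <- data.frame(shape = info$shape, is_oddball = info$pos %in% c(7, 9),
                     run = info$run,
                     block = as.integer(interaction(info$shape, info$run)),
                     position = info$pos)
  data <- array(rnorm(n_ep * n_channels * nt), c(n_ep, n_channels, nt))
  if (shift != 0) {
    w <- if (is.null(oddball_window)) seq_len(nt) else oddball_window
    u <- rep(c(1, -1), length.out = n_channels) * shift
    idx <- which(info$is_oddball)
    for (i in idx) data[i, , w] <- data[i, , w] + u
  }
  epoch_set(data, seq(0, by = 0.004, length.out = nt), info, 250)
}

test_that("block-initial epochs are dropped, oddballs untouched", {
  ep <- tiny_epochs()
  n0 <- sum(ep$info$is_oddball)
  ep6 <- drop_block_initial(ep, 6)
  expect_true(all(ep6$info$position > 6))
  expect_equal(sum(ep6$info$is_oddball), n0)  # oddballs sit beyond position 6
  expect_equal(dim(ep6$data)[1], nrow(ep6$info))
  expect_identical(drop_block_initial(ep, 0)$info, ep$info)
})

test_that("the six run splits are the stated partitions, used in both directions", {
  f <- make_run_folds(1:8)
  expect_length(f, 6)
  for (s in f) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:8)
  }
  key <- sapply(f, function(s) paste(sort(s$train), collapse = ""))
  expect_setequal(key, c("2468", "1357", "5678", "1234", "3478", "1256"))
  ## each partition appears in both directions
  expect_setequal(sapply(f, function(s) paste(sort(s$test), collapse = "")), key)
})

test_that("AUC is rank-based and invariant to monotone transforms", {
  set.seed(40)
  sc <- rnorm(50); y <- sc + rnorm(50) > 0
  a1 <- auc_score(sc, y)
  expect_equal(auc_score(exp(sc * 2), y), a1, tolerance = 1e-12)
  expect_equal(auc_score(rank(sc), y), a1, tolerance = 1e-12)
  expect_identical(auc_score(sc, rep(TRUE, 50)), NA_real_)
  ## perfect separation
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
})

test_that("a planted oddball shift is decoded only inside its window", {
  ep <- tiny_epochs(shift = 2.5, oddball_window = 5:8, seed = 2)
  dec <- time_resolved_oddball_decode(drop_block_initial(ep),
                                      decode_config(smooth_ms = 0))
  expect_equal(dim(dec$auc), c(2L, 12L))
  expect_true(all(dec$auc[, 5:8] > 0.95))
  expect_true(all(abs(dec$auc[, c(1:3, 10:12)] - 0.5) < 0.25))
  ## per-shape training agrees when the signature is shared
  dec2 <- time_resolved_oddball_decode(drop_block_initial(ep),
            decode_config(smooth_ms = 0, per_shape_training = TRUE))
  expect_lt(max(abs(dec2$auc[, 5:8] - dec$auc[, 5:8])), 0.1)
})

test_that("label permutation yields chance-level decoding", {
  ep <- tiny_epochs(n_block = 15, shift = 2.5, oddball_window = 5:8, seed = 3)
  set.seed(7)
  ep$info$is_oddball <- sample(ep$info$is_oddball)
  ## permuted labels break the position structure; decode without dropping
  dec <- time_resolved_oddball_decode(ep, decode_config(smooth_ms = 0))
  expect_gt(mean(dec$auc), 0.45)
  expect_lt(mean(dec$auc), 0.55)
})

test_that("sliding average matches a direct convolution oracle", {
  set.seed(41)
  x <- rnorm(80)
  sm <- sliding_average(x, 100, 250)     # 25-sample centered window
  oracle <- vapply(seq_along(x), function(i) {
    idx <- max(1, i - 12):min(length(x), i + 12)
    mean(x[idx])
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)
  ## constant series unchanged; unit impulse becomes a 1/25 plateau
  expect_equal(sliding_average(rep(3, 50), 100, 250), rep(3, 50))
  imp <- rep(0, 101); imp[51] <- 1
  smi <- sliding_average(imp, 100, 250)
  expect_equal(smi[51], 1 / 25, tolerance = 1e-12)
  expect_equal(sum(smi > 0), 25)
})

test_that("regularity correlation and latency statistics behave on constructed input", {
  ## AUC affine in regularity at one timepoint gives r = 1 there
  reg <- c(0, 2, 5, 9, 14, 18)
  auc <- matrix(0.5, 6, 10)
  auc[, 4] <- 0.5 + 0.01 * reg
  rl <- lapply(1:6, function(i) auc + matrix(rnorm(60, sd = 1e-4), 6))
  rc <- regularity_correlation(rl, reg, n_perm = 256, seed = 1)
  expect_true(all(rc$r[, 4] > 0.999))
  expect_error(regularity_correlation(rl, rep(1, 6)), "constant")
  ## latency: first crossing of the threshold, NA when never crossed
  times <- seq(-0.1, 0.5, by = 0.004)
  a <- matrix(0.5, 2, length(times))
  k0 <- which(times >= 0.2 - 1e-9)[1]
  a[1, k0:length(times)] <- 0.8
  la <- decode_latency(a, times, 0.57)
  expect_equal(unname(la[1]), times[k0])
  expect_true(is.na(la[2]))
  ## slope test: monotone planted latency gradient gives a negative slope
  set.seed(42)
  lat <- t(replicate(10, 0.3 - 0.005 * reg + rnorm(6, sd = 0.005)))
  st <- latency_slope_test(lat, reg)
  expect_lt(st$test$statistic, 0)
  expect_lt(st$test$p.value, 0.05)
  ## participants with undefined latencies are excluded with a warning
  lat[1, ] <- NA
  expect_warning(st2 <- latency_slope_test(lat, reg), "excluded")
  expect_equal(st2$excluded, 1L)
})
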