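## Independent oracles used across tests (deliberately naive implementations)

## exhaustive segment-intersection simplicity oracle: checks every pair of
## edges, treating shared endpoints of adjacent edges as allowed
oracle_is_simple <- function(v) {
  seg <- function(i) rbind(v[i, ], v[i %% 4 + 1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in 1:4) for (j in 1:4) {
    if (abs(i - j) %in% c(0, 1, 3)) next   # same or adjacent edge
    a <- seg(i); b <- seg(j)
    if (inter(a[1, ], a[2, ], b[1, ], b[2, ])) return(FALSE)
  }
  TRUE
}

## brute-force crossnobis: explicit double loop over fold pairs with solve()
oracle_crossnobis <- function(X, Sigma = NULL, scheme = "all-pairs",
                              normalize = TRUE) {
  n <- dim(X)[1]; M <- dim(X)[2]; P <- dim(X)[3]
  Si <- if (is.null(Sigma)) diag(P) else solve(Sigma)
  pr <- utils::combn(n, 2)
  out <- numeric(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    if (scheme == "all-pairs") {
      acc <- 0; cnt <- 0
      for (m in seq_len(M)) for (l in seq_len(M)) {
        if (m >= l) next
        acc <- acc + drop(t(X[i, m, ] - X[j, m, ]) %*% Si %*% (X[i, l, ] - X[j, l, ]))
        cnt <- cnt + 1
      }
      out[k] <- acc / cnt
    } else {
      acc <- 0
      for (m in seq_len(M)) {
        dm <- X[i, m, ] - X[j, m, ]
        rest <- setdiff(seq_len(M), m)
        db <- rowMeans(vapply(rest, function(l) X[i, l, ] - X[j, l, ],
                              numeric(P)))
        acc <- acc + drop(t(dm) %*% Si %*% db)
      }
      out[k] <- acc / M
    }
  }
  if (normalize) out / P else out
}

## naive temporal cluster test with explicit sign-pattern enumeration
oracle_temporal_clusters <- function(x, alpha = 0.05) {
  n <- nrow(x)
  tstat <- function(m) apply(m, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::t.test(col)$statistic
  })
  thr <- stats::qt(1 - alpha, n - 1)
  masses <- function(tv) {
    flag <- !is.na(tv) & tv > thr
    if (!any(flag)) return(numeric(0))
    r <- rle(flag); e <- cumsum(r$lengths); s <- e - r$lengths + 1
    vapply(which(r$values), function(k) sum(tv[s[k]:e[k]]), numeric(1))
  }
  obs <- masses(tstat(x))
  grid <- expand.grid(rep(list(c(-1, 1)), n))
  mx <- apply(grid, 1, function(sg) {
    mm <- masses(tstat(sg * x))
    if (length(mm)) max(mm) else 0
  })
  list(obs = obs, perm_max = mx,
       p = vapply(obs, function(m) sum(mx >= m) / length(mx), numeric(1)))
}

## tiny toy trial table over 3 shapes with hand-computable pooled RDM
toy_trials <- function() {
  data.frame(
    participant = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
    reference = c("a", "b", "a", "c", "b", "c", "a", "b", "a", "c", "b", "c"),
    intruder  = c("b", "a", "c", "a", "c", "b", "b", "a", "c", "a", "c", "b"),
    correct   = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                  FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    rt = c(1000, 1500, 800, 1200, 2000, 1000, 1400, 1100, 900, 1500, 1800, 1250))
}

## hand computation of the pooled empirical RDM for toy_trials()
toy_expected_raw <- function() {
  tr <- toy_trials()
  labs <- c("a", "b", "c")
  val <- function(i, j) {
    ij <- tr$reference == i & tr$intruder == j
    ji <- tr$reference == j & tr$intruder == i
    mean(c(mean(tr$correct[ij]) / mean(tr$rt[ij]),
           mean(tr$correct[ji]) / mean(tr$rt[ji])))
  }
  c(val("a", "b"), val("a", "c"), val("b", "c"))
}

shapes11 <- function() make_reference_shapes()
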