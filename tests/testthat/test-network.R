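test_that("bicor behaves like a robust correlation", {
  set.seed(5)
  x <- matrix(rnorm(4 * 500), 4, 500)
  x[2, ] <- x[1, ]                       # duplicated gene
  R <- bicorMatrix(x)
  expect_equal(R[1, 2], 1, tolerance = 1e-12)
  # Gaussian data without outliers: close to Pearson
  P <- cor(t(x))
  expect_lt(max(abs(R - P)), 0.05)

  # a gross outlier moves bicor less than Pearson
  set.seed(6)
  y <- matrix(rnorm(2 * 60), 2, 60)
  y[2, ] <- 0.8 * y[1, ] + 0.6 * y[2, ]
  r_clean_b <- bicorMatrix(y)[1, 2]
  r_clean_p <- cor(t(y))[1, 2]
  y2 <- y
  y2[2, 1] <- 40                         # inject one gross outlier
  shift_b <- abs(bicorMatrix(y2)[1, 2] - r_clean_b)
  shift_p <- abs(cor(t(y2))[1, 2] - r_clean_p)
  expect_lt(shift_b, shift_p)

  # constant gene: correlation 0 with a flag; zero-MAD gene: Pearson fallback
  z <- rbind(rnorm(30), rep(2, 30))
  Rz <- bicorMatrix(z)
  expect_equal(Rz[1, 2], 0)
  expect_identical(attr(Rz, "degenerate"), "g2")
  zm <- rbind(rnorm(30), c(rep(0, 28), 5, -5))     # MAD 0 but not constant
  expect_warning(Rm <- bicorMatrix(zm), "fallback")
  expect_true(abs(Rm[1, 2]) <= 1)
  expect_error(bicorMatrix(matrix(1:4, 2, 2)), "3 samples")
})

test_that("signedTOM matches the brute-force definition", {
  # perfect anti-correlation: adjacency 0 everywhere, TOM off-diagonal 0
  cneg <- matrix(-1, 3, 3); diag(cneg) <- 1
  t0 <- signedTOM(cneg, beta = 6)
  expect_equal(unname(tomValues(t0)[upper.tri(cneg)]), rep(0, 3))

  # two identical genes in an uncorrelated panel: TOM between them ~ 1
  set.seed(10)
  e <- matrix(rnorm(6 * 200), 6, 200)
  e[2, ] <- e[1, ]
  tid <- signedTOM(bicorMatrix(e), beta = 12)
  expect_gt(tomValues(tid)[1, 2], 0.95)

  # random matrix vs independent triple-loop oracle
  set.seed(11)
  ee <- matrix(rnorm(10 * 40), 10, 40)
  cc <- cor(t(ee))
  dimnames(cc) <- list(paste0("g", 1:10), paste0("g", 1:10))
  tm <- signedTOM(cc, beta = 8)
  expect_lt(max(abs(tomValues(tm) - tom_bruteforce(cc, 8))), 1e-12)
  expect_true(all(tomValues(tm) >= 0 & tomValues(tm) <= 1))
  expect_error(signedTOM(cc, beta = -1), "positive")
})

test_that("setConnectivity sums TOM over the symmetric difference", {
  tm <- matrix(0.05, 4, 4)
  tm[1, 3] <- tm[3, 1] <- 0.4
  tm[1, 4] <- tm[4, 1] <- 0.3
  tm[2, 3] <- tm[3, 2] <- 0.2
  tm[2, 4] <- tm[4, 2] <- 0.1
  diag(tm) <- 1
  tom <- make_tom(tm)
  g <- geneIds(tom)
  expect_equal(setConnectivity(tom, g[1:2], g[2:3]), tm[1, 3])
  expect_equal(setConnectivity(tom, g[1:3], g[2:3]), 0)    # Y subset of X
  expect_equal(setConnectivity(tom, g[1:2], g[3:4]),
               tm[1, 3] + tm[1, 4] + tm[2, 3] + tm[2, 4])
  expect_equal(setConnectivity(tom, g[1:2], g[3:4]),
               setConnectivity(tom, g[3:4], g[1:2]))       # symmetry
  expect_warning(k <- setConnectivity(tom, c(g[1], "zz"), g[3]), "dropped")
  expect_equal(k, tm[1, 3])
  expect_identical(attr(setConnectivity(tom, g[1:2], g[1:2]), "note"),
                   "both residual sets empty")

  # monotonicity: raising a cross entry raises k
  tm2 <- tm; tm2[1, 3] <- tm2[3, 1] <- 0.9
  expect_gt(setConnectivity(make_tom(tm2), g[1:2], g[3:4]),
            setConnectivity(tom, g[1:2], g[3:4]))
})

test_that("connectivityP matches exhaustive enumeration on a small TOM", {
  set.seed(12)
  ee <- matrix(rnorm(30 * 60), 30, 60)
  tom <- signedTOM(bicorMatrix(ee), beta = 4)
  g <- geneIds(tom)
  X <- g[1:2]; Y <- g[3]
  obs <- setConnectivity(tom, X, Y)
  # exhaustive null over every (|X| = 2, |Y| = 1) pair of index sets
  subs <- utils::combn(30, 2)
  kfun <- function(xi, yi) {
    xr <- setdiff(xi, yi); yr <- setdiff(yi, xi)
    if (!length(xr) || !length(yr)) 0 else sum(tomValues(tom)[xr, yr])
  }
  ks <- numeric(ncol(subs) * 30L)
  idx <- 1L
  for (i in seq_len(ncol(subs))) for (j in 1:30) {
    ks[idx] <- kfun(subs[, i], j); idx <- idx + 1L
  }
  p_exact <- mean(ks >= obs)
  cp <- connectivityP(tom, X, Y, n_draws = 400, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(cp$p - p_exact), 3 * se + 1 / 400)

  # off-diagonal-zero TOM: k = 0 everywhere, p-hat 1
  eye <- diag(5)
  cp0 <- connectivityP(make_tom(eye), paste0("g", 1:2), paste0("g", 3:4),
                       n_draws = 100, seed = 1)
  expect_equal(cp0$k, 0)
  expect_equal(cp0$p, 1)
  expect_error(connectivityP(make_tom(eye), paste0("g", 1:3), paste0("g", 3:5),
                             n_draws = 10, seed = 1), "exceeds")
})

test_that("soft-threshold diagnostic reports fit and connectivity per power", {
  set.seed(20)
  sim <- simulateCoexpression(60, 40, moduleSizes = c(20, 20), loading = 0.9,
                              seed = 2)
  d <- softThresholdDiagnostic(bicorMatrix(sim$expr), powers = c(2, 6, 12))
  expect_identical(d$power, c(2, 6, 12))
  expect_true(all(d$mean_k > 0))
  expect_true(all(diff(d$mean_k) < 0))   # connectivity falls with power
})
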