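test_that("tissueWeights carries expression shares and fold-change signs", {
  pan <- make_panel(genes = c("A", "B", "C"), tissues = c("t1", "t2"),
                    p = matrix(0.5, 3, 2),
                    fc = matrix(c(1, 1, 0, -1, -1, 2), 3, 2),
                    ex = matrix(c(10, 90, 50, 0, 10, 50), 3, 2))
  w <- tissueWeights(pan)
  expect_equal(unname(w["A", ]), c(1, 0))          # 100/0 split, sign +
  expect_equal(unname(w["B", ]), c(0.9, -0.1))     # shares (90,10), signs (+,-)
  # log2fc exactly 0: weight 0 but expression still in the denominator
  expect_equal(unname(w["C", ]), c(0, 0.5))
  expect_equal(unname(rowSums(abs(w))[c("A", "B")]), c(1, 1))
})

test_that("tissueWeights excludes zero-expression genes and missing cells", {
  pan <- make_panel(genes = c("A", "B"), tissues = c("t1", "t2"),
                    p = matrix(c(0.5, 0.5, NA, 0.5), 2),
                    fc = matrix(c(1, 1, NA, -1), 2),
                    ex = matrix(c(30, 0, NA, 0), 2))
  w <- tissueWeights(pan)
  expect_identical(attr(w, "excluded"), "B")       # zero total expression
  expect_equal(unname(w["A", ]), c(1, 0))          # missing cell -> weight 0
})

test_that("weighted gene statistics match direct evaluation", {
  expect_equal(weightedGeneStat(0.05, 1), 5.991465, tolerance = 1e-6)
  expect_equal(weightedGeneStat(c(0.01, 0.01), c(0.5, -0.5)), 0)
  expect_equal(weightedGeneStat(c(0.01, 0.01), c(0.9, -0.1)), 7.368273,
               tolerance = 1e-6)
  expect_error(weightedGeneStat(c(0.1, 0.2), 1), "lengths")

  expect_equal(weightedFoldChangeStat(c(1.0, -0.5), c(0.9, -0.1)), 0.95)
  expect_equal(weightedFoldChangeStat(c(3, 3), c(0.5, 0.5)), 3)
  expect_equal(weightedFoldChangeStat(c(1, -2), c(0.3, 0.7)),
               weightedFoldChangeStat(c(-1, 2), c(-0.3, -0.7)))
  expect_error(weightedFoldChangeStat(1, c(1, 2)), "lengths")
})

test_that("f_g respects permutation, scaling and monotonicity properties", {
  set.seed(14)
  p <- runif(6); w <- rnorm(6)
  o <- sample(6)
  expect_equal(weightedGeneStat(p, w), weightedGeneStat(p[o], w[o]))

  # equal positive shares over l tissues give F / l
  l <- 4; pp <- runif(l)
  expect_equal(weightedGeneStat(pp, rep(1 / l, l)), fisherStat(pp) / l)

  # decreasing a p with positive weight never decreases f_g (same-sign weights)
  wpos <- abs(rnorm(5)); wpos <- wpos / sum(wpos)
  p5 <- runif(5)
  f1 <- weightedGeneStat(p5, wpos)
  f2 <- weightedGeneStat(replace(p5, 2, p5[2] / 10), wpos)
  expect_gte(f2, f1)
})

test_that("hypoexponential closed form matches simulation and the gamma case", {
  # equal weights: gamma tail
  w <- c(0.5, 0.5)
  x <- c(1, 3, 8)
  expect_equal(fisherWeightedTailP(x, w),
               pgamma(x, shape = 2, scale = 1, lower.tail = FALSE))
  # distinct weights: compare against direct Monte Carlo of sum 2|w| Exp(1)
  w2 <- c(0.7, -0.2, 0.1)
  set.seed(8)
  sims <- colSums(2 * abs(w2) * matrix(rexp(3 * 200000), 3))
  for (xx in c(0.5, 1.5, 4)) {
    expect_equal(fisherWeightedTailP(xx, w2), mean(sims >= xx),
                 tolerance = 0.01)
  }
  expect_error(fisherWeightedTailP(1, c(0, 0)), "zero")
})

test_that("gene-level resampled p matches the analytic tail on uniform data", {
  set.seed(31)
  n <- 400
  pan <- make_panel(genes = sprintf("g%03d", 1:n), tissues = c("t1", "t2"),
                    p = matrix(runif(2 * n), n),
                    fc = matrix(rnorm(2 * n, 0, 0.05), n),
                    ex = matrix(rlnorm(2 * n), n))
  w <- matrix(0.5, n, 2, dimnames = list(sprintf("g%03d", 1:n), c("t1", "t2")))
  gp <- geneCrossTissueP(pan, w, seed = 77)
  # equal positive weights over 2 tissues: null of f_g is Gamma(2, scale = 1)
  ana <- fisherWeightedTailP(gp$statistic, w[1, ])
  expect_lt(mean(abs(gp$p - ana)), 0.02)
})

test_that("a tissue holding ~all expression dominates the cross-tissue statistic", {
  genes <- "GH-like"
  p <- matrix(c(0.02, 0.5, 0.9), 1, dimnames = list(genes, paste0("t", 1:3)))
  fc <- matrix(c(0.45, 0.1, -0.2), 1, dimnames = dimnames(p))
  ex <- matrix(c(99.96, 0.03, 0.01), 1, dimnames = dimnames(p))
  pan <- TissuePanel(p, fc, ex)
  w <- tissueWeights(pan)
  f <- weightedGeneStat(p[1, ], w[1, ])
  single <- fisherStat(p[1, 1])
  expect_lt(abs(f - single) / single, 0.005)
  # perturbing the minor tissues' p-values barely moves f_g
  p2 <- p; p2[1, 2:3] <- c(1e-4, 1e-4)
  f2 <- weightedGeneStat(p2[1, ], w[1, ])
  expect_lt(abs(f2 - f) / f, 0.005)
})

test_that("enrichCrossTissue scores sets against the gene-level background", {
  cfg <- simConfig(nGenes = 1200, nTissues = 3, nSets = 20, nPlanted = 2,
                   setSizeRange = c(10, 20), seed = 13)
  sim <- simulateDESummaries(cfg)
  w <- tissueWeights(sim$panel)
  gp <- geneCrossTissueP(sim$panel, w, seed = 2)
  expect_equal(nrow(gp), 1200)
  expect_true(all(gp$p >= 1 / (gp$n_draws_used + 1)))
  sets2 <- GeneSetCollection(c(geneSets(sim$sets),
                               list(GHOST = c("NOPE"))))
  xr <- enrichCrossTissue(gp, sets2, seed = 3)
  expect_identical(attr(xr, "skipped"), "GHOST")
  expect_identical(unique(xr$scope), "CROSS")
  planted <- sim$truth$sets$set[sim$truth$sets$planted]
  expect_true(all(xr$fdr[xr$set %in% planted] < 0.05))
  expect_true(all(xr$direction_ratio[xr$set %in% planted] > 1))
})
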