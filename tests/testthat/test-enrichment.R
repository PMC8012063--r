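test_that("fisherStat and foldChangeStat match direct evaluation", {
  expect_equal(fisherStat(c(1, 1, 1)), 0)
  expect_equal(fisherStat(0.05), 5.991465, tolerance = 1e-6)
  expect_equal(fisherStat(c(0.01, 0.02, 0.5)), 18.42068, tolerance = 1e-6)
  expect_error(fisherStat(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisherStat(numeric()), "empty")

  expect_equal(foldChangeStat(c(0, 0)), 0)
  expect_equal(foldChangeStat(c(1.0, -0.5)), 1.5)
  set.seed(1)
  v <- rnorm(20)
  expect_equal(foldChangeStat(v), foldChangeStat(-v))  # sign symmetry

  # monotonicity: F decreases in each p, L increases in each |lfc|
  p <- c(0.2, 0.4, 0.6)
  expect_lt(fisherStat(p), fisherStat(replace(p, 1, 0.1)) )
  expect_gt(foldChangeStat(c(2, 1)), foldChangeStat(c(1.5, 1)))
})

test_that("nullSchedule validates its draw counts", {
  expect_error(nullSchedule(c(1000, 500)), "increasing")
  expect_error(nullSchedule(c(-5, 10)), "increasing|positive")
  expect_identical(as.integer(nullSchedule()), c(1000L, 10000L, 100000L))
})

test_that("empiricalNullP handles degenerate and escalating cases", {
  bg <- seq(0.01, 0.99, length.out = 200)
  # observed 0 (all member p = 1): every null stat >= 0, so p-hat = 1
  r0 <- empiricalNullP(0, bg, m = 5, seed = 1)
  expect_equal(r0$p, 1)
  expect_equal(r0$n_draws, 1000L)

  # observed beyond anything 1000 draws can produce: escalates to the top stage
  rx <- empiricalNullP(1e6, bg, m = 5, seed = 1)
  expect_equal(rx$n_draws, 100000L)
  expect_equal(rx$p, 1 / 100001)

  expect_error(empiricalNullP(1, bg, m = 500, seed = 1), "exceeds")

  # same seed reproduces; custom stat functions are accepted
  a <- empiricalNullP(20, bg, 10, seed = 42)
  b <- empiricalNullP(20, bg, 10, seed = 42)
  expect_identical(a, b)
  fn <- empiricalNullP(0.5, bg, 10, stat = function(x) max(x),
                       schedule = nullSchedule(c(200, 400)), seed = 5)
  expect_true(fn$p > 0 && fn$p <= 1)
})

test_that("empirical null agrees with the chi-square closed form on uniforms", {
  set.seed(21)
  bg <- runif(50000)
  devs <- vapply(1:120, function(i) {
    m <- sample(5:50, 1)
    obs <- fisherStat(sample(bg, m))
    e <- empiricalNullP(obs, bg, m)
    abs(e$p - pchisq(obs, 2 * m, lower.tail = FALSE))
  }, numeric(1))
  expect_lt(mean(devs), 0.02)
})

test_that("background permutation changes p only within Monte-Carlo noise", {
  set.seed(4)
  bg <- runif(2000)
  obs <- fisherStat(runif(12, 0, 0.5))
  p1 <- empiricalNullP(obs, bg, 12, seed = 9)$p
  p2 <- empiricalNullP(obs, sample(bg), 12, seed = 10)$p
  se <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(p1 - p2), 6 * se + 2e-3)
})

test_that("drawing the whole background reproduces the observed statistic", {
  bg <- c(0.1, 0.2, 0.3, 0.4)
  obs <- fisherStat(bg)
  r <- empiricalNullP(obs, bg, m = length(bg),
                      schedule = nullSchedule(c(50, 100)), seed = 1)
  expect_equal(r$p, 1)  # every full draw ties the observed value
})

test_that("directionRatio follows the up/down split of Fisher statistics", {
  r <- directionRatio(c(0.01, 0.5), c(1, -1))
  expect_equal(r$ratio, 6.643856, tolerance = 1e-6)
  expect_equal(r$note, "ok")

  allup <- directionRatio(c(0.1, 0.2), c(0.5, 0.3))
  expect_identical(allup$ratio, Inf)
  expect_identical(allup$note, "all-up")

  sym <- directionRatio(c(0.1, 0.1, 0.4, 0.4), c(1, -1, 1, -1))
  expect_equal(sym$ratio, 1)

  none <- directionRatio(c(0.5, 0.5), c(0, 0))
  expect_identical(none$note, "empty")
})

test_that("enrichTissue recovers a planted set and skips absent ones", {
  cfg <- simConfig(nGenes = 1500, nTissues = 2, nSets = 25, nPlanted = 2,
                   setSizeRange = c(10, 20), seed = 33)
  sim <- simulateDESummaries(cfg)
  extra <- GeneSetCollection(c(geneSets(sim$sets),
                               list(ABSENT = c("NOPE1", "NOPE2"))))
  res <- enrichTissue(sim$panel, extra, "tissue01", seed = 5)
  expect_identical(attr(res, "skipped"), "ABSENT")
  planted <- sim$truth$sets$set[sim$truth$sets$planted]
  hit <- res[res$set %in% planted, ]
  expect_true(all(hit$fdr < 0.05))
  expect_true(all(hit$direction_ratio > 1))       # planted up
  expect_true(all(hit$n_draws_used %in% c(1000L, 10000L, 100000L)))
  expect_true(all(res$empirical_p >= 1 / (res$n_draws_used + 1)))
  expect_error(enrichTissue(sim$panel, extra, "nosuch", seed = 1), "unknown")

  # L method runs on the same panel and flags no direction ratio
  resL <- enrichTissue(sim$panel, sim$sets, "tissue01", method = "L",
                       schedule = nullSchedule(c(500, 1000)), seed = 6)
  expect_true(all(is.na(resL$direction_ratio)))
  expect_true(all(resL$statistic >= 0))
  expect_true(all(resL$set %in% names(sim$sets)))
})
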