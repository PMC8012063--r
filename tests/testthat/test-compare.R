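test_that("overlapTest matches the hypergeometric point computation", {
  uni <- sprintf("g%02d", 1:20)
  A <- uni[1:10]
  res <- overlapTest(A, A, uni, alternative = "greater")
  # right tail is the point mass of the extreme table: 1 / choose(20, 10)
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-9)
  expect_equal(res$p, dhyper(10, 10, 10, 10), tolerance = 1e-12)
  expect_true(res$haldane)
  expect_equal(res$overlap, 10)
  # two-sided summation also picks up the equally extreme mirror table
  expect_equal(overlapTest(A, A, uni)$p, 2 / choose(20, 10), tolerance = 1e-9)

  # expected-overlap-zero case: p ~ 1
  r2 <- overlapTest(uni[1:2], uni[19:20], uni)
  expect_gt(r2$p, 0.5)

  # symmetric in the two sets
  B <- uni[6:14]
  expect_equal(overlapTest(A, B, uni)$p, overlapTest(B, A, uni)$p)

  expect_error(overlapTest(c(A, "zz"), B, uni), "outside")
})

test_that("overlapTest p-values are calibrated for independent random sets", {
  set.seed(40)
  uni <- sprintf("g%03d", 1:400)
  ps <- replicate(200, {
    a <- sample(uni, 100)
    b <- sample(uni, 100)
    overlapTest(a, b, uni)$p
  })
  # discrete exact test: check coverage rather than an exact-uniform KS
  expect_lte(mean(ps <= 0.05), 0.09)
  expect_gte(mean(ps <= 0.05), 0.005)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.7)
})

test_that("directionConcordance counts signs per stratum and pooled", {
  deg <- data.frame(gene = sprintf("g%02d", 1:10), sign = 1)
  ref <- data.frame(gene = sprintf("g%02d", 1:10), sign = 1)
  r <- directionConcordance(deg, ref)
  pooled <- r[r$stratum == "pooled", ]
  expect_equal(pooled$fraction_same, 1)
  expect_equal(pooled$p, 2 * 0.5^10, tolerance = 1e-12)

  ref2 <- ref; ref2$sign[1:5] <- -1
  r2 <- directionConcordance(deg, ref2)
  expect_equal(r2$p[r2$stratum == "pooled"], 1)    # 5 vs 5

  ref3 <- ref; ref3$sign <- -deg$sign              # mirrored reference
  r3 <- directionConcordance(deg, ref3)
  expect_equal(r3$fraction_same[r3$stratum == "pooled"], 0)
  expect_equal(r3$p[r3$stratum == "pooled"], 2 * 0.5^10, tolerance = 1e-12)

  # strata sum to the pooled counts; zero signs are excluded
  deg4 <- data.frame(gene = rep(sprintf("g%02d", 1:6), 2),
                     sign = c(rep(1, 6), rep(-1, 6)),
                     stratum = rep(c("liver", "skin"), each = 6))
  ref4 <- deg4
  ref4$sign[1] <- 0
  r4 <- directionConcordance(deg4, ref4)
  expect_equal(attr(r4, "n_zero_excluded"), 1L)
  pool <- r4[r4$stratum == "pooled", ]
  expect_equal(pool$n_same + pool$n_opposite,
               sum(r4$n_same[r4$stratum != "pooled"]) +
                 sum(r4$n_opposite[r4$stratum != "pooled"]))

  expect_warning(
    expect_null(directionConcordance(
      data.frame(gene = "x", sign = 1), data.frame(gene = "y", sign = 1))),
    "no shared")
})

test_that("weightedCorrelation reduces to Pearson and matches cov.wt", {
  set.seed(50)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  eq <- weightedCorrelation(x, y, rep(1, 40))
  expect_equal(eq$r, cor(x, y), tolerance = 1e-12)
  expect_equal(eq$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  lin <- weightedCorrelation(x, 2 * x + 1, runif(40, 0.5, 2))
  expect_equal(lin$r, 1, tolerance = 1e-12)

  w <- rlnorm(40)
  wc <- weightedCorrelation(x, y, w)
  cw <- cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)  # independent oracle
  expect_equal(wc$r, cw$cor[1, 2], tolerance = 1e-12)

  # invariance: weight rescaling and affine transforms (sign up to slope)
  expect_equal(weightedCorrelation(x, y, 7 * w)$r, wc$r, tolerance = 1e-12)
  expect_equal(weightedCorrelation(3 * x - 2, -4 * y + 1, w)$r, -wc$r,
               tolerance = 1e-12)

  few <- weightedCorrelation(x, y, c(1, 1, rep(0, 38)))
  expect_true(is.na(few$r))
  expect_error(weightedCorrelation(x, y, rep(-1, 40)), "nonnegative")
})
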