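## Downstream comparative stages: set-overlap tests, cross-species direction
## concordance, and expression-weighted fold-change correlation.

#' Two-sided Fisher's exact overlap test for two gene sets
#'
#' Tests whether two gene sets overlap more (or less) than expected within a
#' common universe via the 2x2 hypergeometric exact test. The odds ratio is
#' the sample (unconditional) odds ratio; when a zero cell occurs the
#' Haldane 0.5 correction is applied and flagged.
#'
#' @param setA,setB character vectors of gene symbols, both subsets of
#'   `universe`.
#' @param universe character vector defining the tested gene space, e.g. the
#'   intersected transcript catalog of the compared species.
#' @param alternative `"two.sided"` (default; point-probability summation) or
#'   `"greater"`/`"less"` for one-sided hypergeometric tails.
#' @return data.frame row with `n_a`, `n_b`, `n_universe`, `overlap`,
#'   `odds_ratio`, `haldane` (logical), `p`.
#' @export
overlapTest <- function(setA, setB, universe, alternative = "two.sided") {
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  outA <- setdiff(setA, universe); outB <- setdiff(setB, universe)
  if (length(outA) || length(outB))
    stop("genes outside the universe: ",
         paste(head(c(outA, outB), 10), collapse = ", "), call. = FALSE)
  n11 <- length(intersect(setA, setB))
  n12 <- length(setA) - n11
  n21 <- length(setB) - n11
  n22 <- length(universe) - n11 - n12 - n21
  tab <- matrix(c(n11, n21, n12, n22), 2)
  p <- fisher.test(tab, alternative = alternative)$p.value
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  data.frame(n_a = length(setA), n_b = length(setB),
             n_universe = length(universe), overlap = n11,
             odds_ratio = or, haldane = haldane, p = p)
}

#' Cross-study direction concordance of differentially expressed genes
#'
#' Counts, per stratum (e.g. tissue) and pooled over strata, how many shared
#' genes move in the same vs the opposite direction in two studies, and
#' tests the split against 50:50 with the exact two-sided binomial test.
#' Genes with zero fold-change in either table are excluded and reported.
#'
#' @param degTable data.frame with columns `gene`, `sign` (numeric, sign of
#'   the fold-change) and optionally `stratum`.
#' @param referenceTable data.frame with columns `gene`, `sign` (and
#'   `stratum` if `degTable` has one; matching is within stratum then).
#' @return data.frame with one row per stratum plus a `"pooled"` row:
#'   `stratum`, `n_same`, `n_opposite`, `fraction_same`, `p`. Attribute
#'   `"n_zero_excluded"` counts excluded zero-sign genes. `NULL` with a
#'   warning when no genes are shared.
#' @export
directionConcordance <- function(degTable, referenceTable) {
  has_strata <- "stratum" %in% colnames(degTable)
  if (!has_strata) {
    degTable$stratum <- "all"
    referenceTable$stratum <- "all"
  }
  key_a <- paste(degTable$stratum, degTable$gene)
  key_b <- paste(referenceTable$stratum, referenceTable$gene)
  idx <- match(key_a, key_b)
  shared <- !is.na(idx)
  if (!any(shared)) {
    warning("no shared genes between the two tables")
    return(NULL)
  }
  sa <- sign(degTable$sign[shared])
  sb <- sign(referenceTable$sign[idx[shared]])
  strat <- degTable$stratum[shared]
  nonzero <- sa != 0 & sb != 0
  n_zero <- sum(!nonzero)
  sa <- sa[nonzero]; sb <- sb[nonzero]; strat <- strat[nonzero]
  one <- function(label, same, total) {
    p <- if (total > 0) binom.test(same, total, p = 0.5)$p.value else NA_real_
    data.frame(stratum = label, n_same = same, n_opposite = total - same,
               fraction_same = if (total > 0) same / total else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }
  agree <- sa == sb
  rows <- lapply(unique(strat), function(s)
    one(s, sum(agree[strat == s]), sum(strat == s)))
  rows <- c(rows, list(one("pooled", sum(agree), length(agree))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_zero_excluded") <- n_zero
  out
}

#' Weighted Pearson correlation with effective-sample-size p-value
#'
#' Pearson correlation computed with weighted means and (co)variances —
#' e.g. fold-changes weighted by a reference study's baseMean expression.
#' The p-value uses the t approximation with effective sample size
#' `(sum w)^2 / sum(w^2)`. Zero-weight points are dropped.
#'
#' @param x,y aligned finite numeric vectors.
#' @param weights nonnegative weights, not all zero.
#' @return list with `r`, `p`, `n_effective`, `n_used`; `r` and `p` are `NA`
#'   when fewer than 3 points carry positive weight.
#' @export
weightedCorrelation <- function(x, y, weights) {
  stopifnot(length(x) == length(y), length(x) == length(weights))
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  keep <- weights > 0 & is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; w <- weights[keep]
  if (length(x) < 3)
    return(list(r = NA_real_, p = NA_real_, n_effective = NA_real_,
                n_used = length(x)))
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cov_xy <- sum(w * (x - mx) * (y - my)) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  r <- cov_xy / sqrt(vx * vy)
  n_eff <- sw^2 / sum(w^2)
  p <- if (n_eff > 2 && abs(r) < 1) {
    tval <- r * sqrt((n_eff - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n_eff - 2)
  } else if (abs(r) >= 1) 0 else NA_real_
  list(r = r, p = p, n_effective = n_eff, n_used = length(x))
}
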