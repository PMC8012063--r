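## Expression-weighted cross-tissue gene statistics.
##
## A gene's per-tissue p-values are combined into one statistic
##   f_g = | 2 * sum_t log(p_gt) * w_gt |,
##   w_gt = meanExpr_gt * sgn(log2FC_gt) / sum_t meanExpr_gt,
## so tissues carrying the gene's expression dominate and direction-
## consistent regulation is rewarded (sign conflicts cancel). The
## fold-change analogue is l_g = | sum_t log2FC_gt * w_gt |.

#' Expression-share, sign-carrying cross-tissue weights
#'
#' Computes the weight matrix `w\[g, t\] = meanExpr * sgn(log2FC) /
#' rowSums(meanExpr)`. Missing (gene, tissue) cells get weight 0 and are
#' excluded from the denominator; cells with log2FC exactly 0 get weight 0
#' but their expression still counts in the denominator. Genes with zero
#' total expression are excluded and reported.
#'
#' @param panel a [TissuePanel-class].
#' @return Signed numeric genes x tissues matrix (rows restricted to genes
#'   with positive total expression); `sum(abs(w))` is 1 per row when no
#'   cell is missing or sign-zero. Attribute `"excluded"` lists dropped
#'   genes.
#' @export
tissueWeights <- function(panel) {
  ex <- meanExpr(panel)
  fc <- foldChanges(panel)
  ex0 <- ex
  ex0[is.na(ex0)] <- 0
  tot <- rowSums(ex0)
  keep <- tot > 0
  w <- ex0[keep, , drop = FALSE] * sign(ifelse(is.na(fc[keep, , drop = FALSE]),
                                               0, fc[keep, , drop = FALSE]))
  w <- w / tot[keep]
  attr(w, "excluded") <- geneIds(panel)[!keep]
  w
}

#' Weighted cross-tissue Fisher-type gene statistic
#'
#' `f_g = |2 * sum(log(p) * w)|` over a gene's tissues. With a single tissue
#' and weight 1 this reduces to the one-p Fisher statistic `-2 log p`;
#' perfect sign conflict with equal shares cancels to 0.
#'
#' @param pvals per-tissue p-values in (0, 1]; `NA` allowed where the weight
#'   is 0.
#' @param weights aligned signed weights (see [tissueWeights()]).
#' @return Nonnegative scalar.
#' @examples
#' weightedGeneStat(c(0.01, 0.01), c(0.9, -0.1)) # 7.3683
#' @export
weightedGeneStat <- function(pvals, weights) {
  if (length(pvals) != length(weights))
    stop("pvals and weights lengths differ", call. = FALSE)
  active <- weights != 0
  if (any(is.na(pvals[active])))
    stop("missing p-value where weight is nonzero", call. = FALSE)
  if (any(pvals[active] <= 0 | pvals[active] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  abs(2 * sum(log(pvals[active]) * weights[active]))
}

#' Weighted cross-tissue fold-change gene statistic
#'
#' `l_g = |sum(log2FC * w)|`, the effect-size analogue of
#' [weightedGeneStat()].
#'
#' @param log2fcs per-tissue log2 fold-changes.
#' @param weights aligned signed weights.
#' @return Nonnegative scalar.
#' @examples
#' weightedFoldChangeStat(c(1, -0.5), c(0.9, -0.1)) # 0.95
#' @export
weightedFoldChangeStat <- function(log2fcs, weights) {
  if (length(log2fcs) != length(weights))
    stop("log2fcs and weights lengths differ", call. = FALSE)
  active <- weights != 0
  if (any(is.na(log2fcs[active])))
    stop("missing fold-change where weight is nonzero", call. = FALSE)
  abs(sum(log2fcs[active] * weights[active]))
}

#' Analytic tail of the weighted Fisher statistic under uniform nulls
#'
#' Under independent Uniform(0,1) p-values and weights of one sign,
#' `f_g = sum_t 2|w_t| * Exp(1)`, a hypoexponential variable. This closed
#' form (gamma when all |w| are equal, partial-fraction hypoexponential when
#' all are distinct) serves as an independent cross-check of the resampled
#' null of [geneCrossTissueP()].
#'
#' @param x statistic value(s).
#' @param weights signed weights; zeros dropped.
#' @return `P(f_g >= x)` under the independence null.
#' @export
fisherWeightedTailP <- function(x, weights) {
  theta <- 2 * abs(weights[weights != 0])
  if (!length(theta)) stop("all weights are zero", call. = FALSE)
  l <- length(theta)
  if (max(theta) - min(theta) < 1e-12 * max(theta))
    return(pgamma(x, shape = l, scale = theta[1], lower.tail = FALSE))
  if (any(duplicated(signif(theta, 10))))
    stop("tied non-equal |weights|: no closed form implemented; use resampling",
         call. = FALSE)
  # partial-fraction coefficients c_t = prod_{s != t} theta_t / (theta_t - theta_s)
  coefs <- vapply(seq_len(l), function(t)
    prod(theta[t] / (theta[t] - theta[-t])), numeric(1))
  sapply(x, function(xx) min(1, max(0, sum(coefs * exp(-xx / theta)))))
}

#' Cross-tissue gene p-values from per-tissue background resampling
#'
#' For every gene, null statistics are generated by redrawing, per tissue, a
#' p-value (or log2FC for `statKind = "l"`) uniformly from that tissue's
#' observed background while holding the gene's weights fixed; the p-value is
#' the right-tail frequency `(r + 1) / (N + 1)`, escalated through
#' `schedule` like the set-level nulls. Tissues with weight 0 contribute
#' nothing to either the statistic or the null.
#'
#' @param panel a [TissuePanel-class].
#' @param weights weight matrix from [tissueWeights()] on the same panel.
#' @param statKind `"f"` (weighted log-p statistic) or `"l"` (weighted
#'   fold-change statistic).
#' @param schedule a [nullSchedule()].
#' @param seed optional integer seed.
#' @return data.frame with one row per weighted gene: `gene`, `statistic`,
#'   `p`, `signed_sum` (the signed weighted fold-change sum used for
#'   direction calls), `n_tissues_used`, `n_draws_used`.
#' @export
geneCrossTissueP <- function(panel, weights, statKind = c("f", "l"),
                             schedule = nullSchedule(), seed = NULL) {
  statKind <- match.arg(statKind)
  genes <- rownames(weights)
  p <- pValues(panel)[genes, , drop = FALSE]
  fc <- foldChanges(panel)[genes, , drop = FALSE]
  vals <- if (statKind == "f") log(p) else fc
  w <- weights
  wa <- ifelse(w == 0, 0, w)
  v0 <- vals
  v0[w == 0] <- 0           # inactive tissues contribute nothing
  v0[is.na(v0)] <- 0
  obs <- abs((if (statKind == "f") 2 else 1) * rowSums(v0 * wa))
  signed_fc <- {
    fc0 <- fc
    fc0[w == 0] <- 0
    fc0[is.na(fc0)] <- 0
    rowSums(fc0 * wa)
  }
  # Per-tissue backgrounds over genes quantified in that tissue.
  bgs <- lapply(seq_len(ncol(p)), function(t) {
    b <- vals[, t]
    b[!is.na(b)]
  })
  G <- length(genes)
  scale_fac <- if (statKind == "f") 2 else 1
  with_seed_or_not(seed, {
    phat <- rep(NA_real_, G)
    ndraws <- rep(NA_integer_, G)
    todo <- seq_len(G)
    for (s in seq_along(schedule)) {
      N <- schedule[s]
      g <- length(todo)
      S <- matrix(0, g, N)
      for (t in seq_len(ncol(p))) {
        wcol <- wa[todo, t]
        if (all(wcol == 0) || !length(bgs[[t]])) next
        draws <- matrix(sample(bgs[[t]], g * N, replace = TRUE), g, N)
        S <- S + wcol * draws
      }
      nullstat <- abs(scale_fac * S)
      r <- rowSums(nullstat >= obs[todo])
      phat[todo] <- (r + 1) / (N + 1)
      ndraws[todo] <- N
      todo <- todo[phat[todo] <= 1 / N]
      if (!length(todo) || s == length(schedule)) break
    }
    data.frame(gene = genes, statistic = obs, p = phat,
               signed_sum = signed_fc,
               n_tissues_used = rowSums(wa != 0),
               n_draws_used = ndraws, stringsAsFactors = FALSE)
  })
}

#' Pathway enrichment on cross-tissue gene p-values
#'
#' Applies the same machinery as [enrichTissue()] with scope `"CROSS"`: the
#' background is the full vector of cross-tissue gene p-values, the set
#' statistic is Fisher's combination of member-gene p-values, and BH-FDR is
#' taken across sets. The direction ratio uses the sign of each gene's
#' weighted fold-change sum.
#'
#' @param geneP result of [geneCrossTissueP()].
#' @param sets a [GeneSetCollection-class].
#' @param schedule a [nullSchedule()].
#' @param seed optional integer seed.
#' @return data.frame as in [enrichTissue()] with `scope = "CROSS"`; sets
#'   without scored genes are skipped and listed in the `"skipped"`
#'   attribute.
#' @export
enrichCrossTissue <- function(geneP, sets, schedule = nullSchedule(),
                              seed = NULL) {
  background <- geneP$p
  names(background) <- geneP$gene
  direction <- geneP$signed_sum
  names(direction) <- geneP$gene
  res <- with_seed_or_not(seed, {
    rows <- lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], geneP$gene)
      m <- length(members)
      if (m == 0L) return(NULL)
      obs <- fisherStat(background[members])
      nullp <- empiricalNullP(obs, background, m, stat = "fisher",
                              schedule = schedule, seed = NULL)
      dr <- directionRatio(background[members], direction[members])
      data.frame(set = nm, scope = "CROSS", statistic_kind = "F",
                 statistic = obs, empirical_p = nullp$p, fdr = NA_real_,
                 direction_ratio = dr$ratio, ratio_note = dr$note,
                 n_draws_used = nullp$n_draws, m_effective = m,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  skipped <- setdiff(names(sets), res$set)
  if (!is.null(res) && nrow(res)) {
    res$fdr <- bhFdr(res$empirical_p)
    rownames(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  res
}
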