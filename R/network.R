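## Signed co-expression network: biweight midcorrelation, topological
## overlap, and gene-set pair connectivity with a one-sided empirical null.

# Tukey-biweight transformed rows for bicor: each row of `expr` becomes
# (x - med) * (1 - u^2)^2 on |u| < 1, u = (x - med) / (9 * MAD), with the
# per-side maxPOutliers quantile cap, then unit-normalised. Rows with zero
# MAD fall back to centred (Pearson) values; constant rows come back as
# all-zero and are flagged.
.bicor_rows <- function(expr, max_p_outliers) {
  g <- nrow(expr)
  A <- matrix(0, g, ncol(expr), dimnames = dimnames(expr))
  fallback <- degenerate <- logical(g)
  for (i in seq_len(g)) {
    x <- expr[i, ]
    med <- median(x)
    madx <- mad(x, constant = 1)
    if (madx == 0) {
      cx <- x - mean(x)
      if (all(cx == 0)) { degenerate[i] <- TRUE; next }
      fallback[i] <- TRUE
      A[i, ] <- cx / sqrt(sum(cx^2))
      next
    }
    u <- (x - med) / (9 * madx)
    if (max_p_outliers < 0.5) {
      qq <- quantile(x, probs = c(max_p_outliers, 1 - max_p_outliers),
                     names = FALSE, type = 8)
      uL <- (qq[1] - med) / (9 * madx)
      uH <- (qq[2] - med) / (9 * madx)
      neg <- u < 0
      if (uL < -1) u[neg] <- u[neg] / (-uL)   # cap: at most maxPOutliers low-side outliers
      if (uH > 1) u[!neg] <- u[!neg] / uH
    }
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- (x - med) * w
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) {
      cx <- x - mean(x)
      fallback[i] <- TRUE
      A[i, ] <- cx / sqrt(sum(cx^2))
    } else A[i, ] <- a / nrm
  }
  list(A = A, fallback = fallback, degenerate = degenerate)
}

#' Biweight midcorrelation matrix
#'
#' Robust pairwise correlation of gene expression rows using Tukey biweights
#' around the median, with the per-side outlier cap `max_p_outliers`: the
#' weighting is rescaled so that at most that fraction of samples on either
#' side of the median can receive zero weight. Genes with zero median
#' absolute deviation fall back to Pearson with a warning; genes that are
#' outright constant get correlation 0 and are flagged.
#'
#' @param expr genes x samples numeric matrix, at least 3 samples.
#' @param max_p_outliers per-side outlier proportion cap (default 0.1).
#' @return Symmetric correlation matrix in \[-1, 1\] with unit diagonal;
#'   attributes `"fallback"` and `"degenerate"` name the affected genes.
#' @export
bicorMatrix <- function(expr, max_p_outliers = 0.1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  if (any(!is.finite(expr))) stop("expression values must be finite", call. = FALSE)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  b <- .bicor_rows(expr, max_p_outliers)
  if (any(b$fallback))
    warning("Pearson fallback for zero-MAD gene(s): ",
            paste(rownames(expr)[b$fallback], collapse = ", "))
  R <- tcrossprod(b$A)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  if (any(b$degenerate)) {
    R[b$degenerate, ] <- 0
    R[, b$degenerate] <- 0
    diag(R) <- 1
  }
  attr(R, "fallback") <- rownames(expr)[b$fallback]
  attr(R, "degenerate") <- rownames(expr)[b$degenerate]
  R
}

#' Signed topological overlap matrix
#'
#' Builds the signed soft-threshold adjacency `a_ij = ((1 + cor_ij)/2)^beta`
#' (diagonal excluded from all internal sums) and the standard topological
#' overlap `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_u a_iu`. The reported diagonal is 1.
#'
#' @param corr symmetric correlation matrix in \[-1, 1\].
#' @param beta positive soft-threshold power (default 26, suited to signed
#'   networks).
#' @param corType label recorded in the result (provenance only).
#' @return A [TOMatrix-class].
#' @export
signedTOM <- function(corr, beta = 26, corType = "bicor") {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  corr <- as.matrix(corr)
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("g", seq_len(nrow(corr)))
  }
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2   # symmetrise away float noise
  new("TOMatrix", tom = tom, beta = as.numeric(beta), corType = corType)
}

#' Connectivity between two gene sets in a TOM
#'
#' `k_XY = sum over x in X\\Y, y in Y\\X of tom\[x, y\]`: total topological
#' overlap between the non-shared members of the two sets. Zero when either
#' residual set is empty after removing the overlap (e.g. nested sets).
#'
#' @param tom a [TOMatrix-class].
#' @param X,Y character vectors of gene ids (unknown genes dropped with a
#'   warning).
#' @return Nonnegative scalar; `NA` with attribute `"note"` when both
#'   residual sets are empty.
#' @export
setConnectivity <- function(tom, X, Y) {
  ids <- geneIds(tom)
  drop <- setdiff(union(X, Y), ids)
  if (length(drop))
    warning("genes absent from TOM dropped: ", paste(drop, collapse = ", "))
  X <- intersect(X, ids); Y <- intersect(Y, ids)
  xr <- setdiff(X, Y); yr <- setdiff(Y, X)
  if (!length(xr) && !length(yr))
    return(structure(NA_real_, note = "both residual sets empty"))
  if (!length(xr) || !length(yr)) return(0)
  sum(tomValues(tom)[xr, yr, drop = FALSE])
}

#' One-sided empirical p-value for set-pair connectivity
#'
#' Null connectivities come from randomly drawing, per draw, an index set of
#' size |X| and one of size |Y| (each without replacement from all TOM
#' genes, independently of each other, so the two drawn sets may intersect)
#' and applying exactly the observed-statistic computation including the
#' symmetric-difference restriction. The right-tail p is
#' `(r + 1) / (n_draws + 1)`.
#'
#' @param tom a [TOMatrix-class].
#' @param X,Y observed gene sets.
#' @param n_draws number of null pairs (default 10000).
#' @param seed optional integer seed.
#' @return list with `k` (observed connectivity), `p` (one-sided empirical
#'   p), `n_draws`, and residual sizes `n_x`, `n_y`.
#' @export
connectivityP <- function(tom, X, Y, n_draws = 10000, seed = NULL) {
  ids <- geneIds(tom)
  X <- intersect(X, ids); Y <- intersect(Y, ids)
  if (length(X) + length(Y) > length(ids))
    stop("|X| + |Y| exceeds the number of genes in the TOM", call. = FALSE)
  obs <- setConnectivity(tom, X, Y)
  tm <- tomValues(tom)
  n <- length(ids)
  nx <- length(X); ny <- length(Y)
  nulls <- with_seed_or_not(seed, {
    vapply(seq_len(n_draws), function(i) {
      xi <- sample.int(n, nx)
      yi <- sample.int(n, ny)
      xr <- setdiff(xi, yi); yr <- setdiff(yi, xi)
      if (!length(xr) || !length(yr)) 0 else sum(tm[xr, yr])
    }, numeric(1))
  })
  p <- (sum(nulls >= obs) + 1) / (n_draws + 1)
  list(k = as.numeric(obs), p = p, n_draws = n_draws,
       n_x = length(setdiff(X, Y)), n_y = length(setdiff(Y, X)))
}

#' Scale-free fit diagnostic across candidate soft powers
#'
#' For each candidate power, reports the linear-model R^2 of log10 p(k) vs
#' log10 k over binned connectivities and the mean connectivity — the usual
#' diagnostic used to pick a soft threshold. Reported only; no power is
#' auto-chosen.
#'
#' @param corr correlation matrix.
#' @param powers candidate powers.
#' @param n_breaks connectivity histogram bins.
#' @return data.frame with `power`, `sft_r2`, `mean_k`.
#' @export
softThresholdDiagnostic <- function(corr, powers = c(1, seq(2, 30, 2)),
                                    n_breaks = 10) {
  out <- lapply(powers, function(b) {
    a <- ((1 + corr) / 2)^b
    diag(a) <- 0
    k <- rowSums(a)
    br <- seq(min(k), max(k), length.out = n_breaks + 1)
    cut_k <- cut(k, breaks = br, include.lowest = TRUE)
    pk <- tapply(k, cut_k, length) / length(k)
    mid <- (br[-1] + br[-length(br)]) / 2
    keep <- !is.na(pk) & pk > 0 & mid > 0
    r2 <- if (sum(keep) >= 3) {
      fit <- stats::lm(log10(pk[keep]) ~ log10(mid[keep]))
      summary(fit)$r.squared
    } else NA_real_
    data.frame(power = b, sft_r2 = r2, mean_k = mean(k))
  })
  do.call(rbind, out)
}
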