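## Per-tissue threshold-free gene-set enrichment.
##
## The set-level statistic is either Fisher's combination F = -2 * sum(log p)
## over the member genes, or the fold-change analogue L = sum(|log2FC|).
## Because gene-level tests in one tissue are not independent, significance
## comes from an empirically resampled null: repeatedly draw m genes (the set
## size) without replacement from the tissue-wide background, recompute the
## statistic, and take the right-tail frequency. Draws escalate through a
## schedule (1000, 10,000, 100,000 by default) whenever the estimate hits the
## resolution bound of the current stage.

#' Fisher combination statistic
#'
#' `-2 * sum(log(p))` over a vector of p-values; zero iff all p equal 1.
#' Large values indicate enrichment of small p-values.
#'
#' @param pvals numeric vector of p-values in (0, 1]; p = 0 must have been
#'   clamped at ingest (see [readDETable()]).
#' @return Nonnegative scalar.
#' @examples
#' fisherStat(c(0.01, 0.02, 0.5)) # 18.4207
#' @export
fisherStat <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  -2 * sum(log(pvals))
}

#' Fold-change combination statistic
#'
#' Sum of absolute log2 fold-changes over the member genes; a threshold-free
#' effect-size analogue of [fisherStat()].
#'
#' @param log2fcs numeric vector of log2 fold-changes.
#' @return Nonnegative scalar.
#' @export
foldChangeStat <- function(log2fcs) {
  if (!length(log2fcs)) stop("empty fold-change vector", call. = FALSE)
  sum(abs(log2fcs))
}

#' Escalating draw schedule for empirical nulls
#'
#' @param draws strictly increasing positive integers; at each stage the
#'   null is re-estimated with that many fresh draws, and the procedure
#'   escalates while the p estimate sits at (or below) the resolution bound
#'   1/N of the stage just completed.
#' @return Validated integer vector (class `nullSchedule`).
#' @export
nullSchedule <- function(draws = c(1000L, 10000L, 100000L)) {
  draws <- as.integer(draws)
  if (any(draws <= 0L) || any(diff(draws) <= 0L))
    stop("schedule must be strictly increasing positive integers", call. = FALSE)
  structure(draws, class = "nullSchedule")
}

# Null statistics for N draws of size m from `tvals` (already transformed so
# the statistic is a plain column sum), drawn without replacement per draw.
.null_sum_stats <- function(tvals, m, N) {
  .null_sum_draws_cpp(tvals, as.integer(m), as.integer(N))
}

#' Empirical null p-value with draw escalation
#'
#' Estimates the right-tail probability of `observed` under the resampling
#' null: draws of `m` background genes without replacement, statistic
#' recomputed per draw, `p = (r + 1) / (N + 1)` with `r` the number of null
#' statistics >= observed. Stages are re-run with fresh draws while the
#' estimate remains at or below the previous stage's resolution bound.
#'
#' @param observed observed statistic value.
#' @param background full per-tissue vector of gene-level inputs: p-values
#'   for `stat = "fisher"`, log2 fold-changes for `stat = "sumabs"`.
#' @param m set size to draw.
#' @param stat `"fisher"` ([fisherStat()]), `"sumabs"` ([foldChangeStat()]),
#'   or any function mapping a drawn vector to a scalar.
#' @param schedule a [nullSchedule()].
#' @param seed optional integer; fixes the draw sequence.
#' @return list with `p` (empirical p-value) and `n_draws` (draws of the
#'   final stage).
#' @export
empiricalNullP <- function(observed, background, m, stat = "fisher",
                           schedule = nullSchedule(), seed = NULL) {
  n <- length(background)
  if (m > n) stop("set size m exceeds background size", call. = FALSE)
  if (is.function(stat)) {
    raw <- stat
    draw_fun <- function(N)
      vapply(seq_len(N), function(i) raw(background[sample.int(n, m)]),
             numeric(1))
  } else {
    tvals <- switch(match.arg(stat, c("fisher", "sumabs")),
                    fisher = -2 * log(background),
                    sumabs = abs(background))
    draw_fun <- function(N) .null_sum_stats(tvals, m, N)
  }
  with_seed_or_not(seed, {
    p <- NA_real_
    n_used <- NA_integer_
    for (s in seq_along(schedule)) {
      N <- schedule[s]
      nulls <- draw_fun(N)
      p <- (sum(nulls >= observed) + 1) / (N + 1)
      n_used <- N
      if (p > 1 / N) break  # resolution sufficient; no escalation
    }
    list(p = p, n_draws = n_used)
  })
}

#' Up/down direction ratio of a gene set
#'
#' Splits member genes by fold-change sign, computes the Fisher statistic on
#' each subset, and reports `F_up / F_down` as an indicator of net up- (> 1)
#' or down-regulation (< 1). Genes with log2FC exactly 0 join neither subset.
#'
#' @param pvals,log2fcs aligned member-gene vectors.
#' @return list with `ratio` (may be `Inf` when only the up subset carries
#'   signal, 0 for the mirror case, `NA` when undefined) and `note` — one of
#'   `"ok"`, `"all-up"`, `"all-down"`, `"down-stat-zero"`, `"empty"`.
#' @examples
#' directionRatio(c(0.01, 0.5), c(1, -1)) # ratio 6.6439
#' @export
directionRatio <- function(pvals, log2fcs) {
  stopifnot(length(pvals) == length(log2fcs))
  keep <- !is.na(pvals) & !is.na(log2fcs)
  pvals <- pvals[keep]; log2fcs <- log2fcs[keep]
  up <- log2fcs > 0
  dn <- log2fcs < 0
  if (!any(up) && !any(dn)) return(list(ratio = NA_real_, note = "empty"))
  if (!any(dn)) return(list(ratio = Inf, note = "all-up"))
  if (!any(up)) return(list(ratio = 0, note = "all-down"))
  f_up <- fisherStat(pvals[up])
  f_dn <- fisherStat(pvals[dn])
  if (f_dn == 0) return(list(ratio = Inf, note = "down-stat-zero"))
  list(ratio = f_up / f_dn, note = "ok")
}

#' Per-tissue gene-set enrichment against the resampling null
#'
#' For each set, member genes with data in the tissue define the observed
#' statistic; the null is estimated by [empiricalNullP()] over the full
#' background of genes quantified in that tissue. BH-FDR is applied across
#' sets within the tissue. For the Fisher method the direction ratio
#' ([directionRatio()]) is reported per set.
#'
#' @param panel a [TissuePanel-class].
#' @param sets a [GeneSetCollection-class].
#' @param tissue tissue name present in the panel.
#' @param method `"F"` (Fisher on p-values) or `"L"` (sum of |log2FC|).
#' @param schedule a [nullSchedule()].
#' @param seed optional integer seed; fixes all draws of the call.
#' @return data.frame with columns `set`, `scope`, `statistic_kind`,
#'   `statistic`, `empirical_p`, `fdr`, `direction_ratio`, `ratio_note`,
#'   `n_draws_used`, `m_effective`. Sets without any member quantified in
#'   the tissue are skipped and listed in the `"skipped"` attribute.
#' @export
enrichTissue <- function(panel, sets, tissue, method = c("F", "L"),
                         schedule = nullSchedule(), seed = NULL) {
  method <- match.arg(method)
  if (!tissue %in% tissueNames(panel))
    stop("unknown tissue: ", tissue, call. = FALSE)
  p_t <- pValues(panel)[, tissue]
  fc_t <- foldChanges(panel)[, tissue]
  quantified <- !is.na(p_t) & !is.na(fc_t)
  background <- if (method == "F") p_t[quantified] else fc_t[quantified]
  genes_bg <- geneIds(panel)[quantified]
  res <- with_seed_or_not(seed, {
    rows <- lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], genes_bg)
      m <- length(members)
      if (m == 0L) return(NULL)
      obs <- if (method == "F") fisherStat(p_t[members])
             else foldChangeStat(fc_t[members])
      nullp <- empiricalNullP(obs, background, m,
                              stat = if (method == "F") "fisher" else "sumabs",
                              schedule = schedule, seed = NULL)
      dr <- if (method == "F") directionRatio(p_t[members], fc_t[members])
            else list(ratio = NA_real_, note = "not-computed")
      data.frame(set = nm, scope = tissue, statistic_kind = method,
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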