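## Synthetic inputs with known ground truth: multi-tissue DE summary panels
## with planted pathway-coherent effects, co-expression matrices with planted
## module structure, and cohorts under status-specific constant hazards.
##
## Defaults emulate the structure of a large multi-tissue breeder/non-breeder
## contrast: ~15,000 genes x 16 tissues, uniform null p-values, planted
## shifts of subtle magnitude (mean |log2FC| 0.07, about a 5% change), and
## Dirichlet expression profiles that allow near-point-mass tissue
## specificity.

#' Simulation configuration for DE summary panels
#'
#' @param nGenes,nTissues panel dimensions (defaults 15000 x 16, the scale
#'   of a full multi-tissue study).
#' @param nSets number of gene sets in the generated collection.
#' @param setSizeRange inclusive range of set sizes (uniform).
#' @param nPlanted number of sets carrying a planted effect (drawn from
#'   disjoint gene pools so ground truth stays exact).
#' @param plantedTissues tissue indices affected by the planted effects, or
#'   `"all"`.
#' @param alpha Beta(alpha, 1) shape for signal-gene p-values (alpha < 1;
#'   smaller = stronger signal; default 0.1).
#' @param meanAbsLfc mean |log2FC| of planted cells (default 0.07, i.e. a
#'   roughly 5% expression shift).
#' @param directionConsistency probability that a signal gene keeps its
#'   set-level direction in each affected tissue (1 = perfectly consistent,
#'   0.5 = random signs); scalar or one value per planted set.
#' @param plantedDirection `+1`, `-1`, or `"random"` per planted set.
#' @param sigmaNullLfc standard deviation of null log2 fold-changes.
#' @param exprMeanlog,exprSdlog log-normal parameters of per-gene total
#'   expression.
#' @param dirichletAlpha concentration of the per-gene Dirichlet expression
#'   profile across tissues; small values produce tissue-specific genes. The
#'   default 0.1 yields, at 16 tissues, a small minority of genes (~0.1%)
#'   with >= 99% of their expression in one tissue — the hormone-gene
#'   extreme — and a few percent above 90%.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return Validated configuration list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 15000, nTissues = 16, nSets = 200,
                      setSizeRange = c(10, 50), nPlanted = 0,
                      plantedTissues = "all", alpha = 0.1,
                      meanAbsLfc = 0.07, directionConsistency = 1,
                      plantedDirection = 1, sigmaNullLfc = 0.05,
                      exprMeanlog = log(500), exprSdlog = 1.5,
                      dirichletAlpha = 0.1, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
              nSets = as.integer(nSets),
              setSizeRange = as.integer(setSizeRange),
              nPlanted = as.integer(nPlanted),
              plantedTissues = plantedTissues, alpha = alpha,
              meanAbsLfc = meanAbsLfc,
              directionConsistency = directionConsistency,
              plantedDirection = plantedDirection,
              sigmaNullLfc = sigmaNullLfc, exprMeanlog = exprMeanlog,
              exprSdlog = exprSdlog, dirichletAlpha = dirichletAlpha,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nGenes > 0, nTissues > 0, nSets >= 0,
              setSizeRange[1] >= 1, setSizeRange[2] >= setSizeRange[1],
              nPlanted <= nSets, alpha > 0, alpha < 1,
              all(directionConsistency >= 0), all(directionConsistency <= 1),
              sigmaNullLfc >= 0, dirichletAlpha > 0)
  })
  if (cfg$nPlanted * cfg$setSizeRange[2] > cfg$nGenes)
    stop("config requests more signal genes than nGenes", call. = FALSE)
  structure(cfg, class = "simConfig")
}

.rdirichlet1 <- function(n, alpha, k) {
  g <- matrix(rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Simulate multi-tissue DE summary tables with planted set effects
#'
#' Null genes get p ~ Uniform(0, 1) and log2FC ~ Normal(0, sigmaNullLfc) in
#' every tissue. Genes of planted sets get, in the affected tissues,
#' p ~ Beta(alpha, 1) and a signed log2FC whose sign follows the set
#' direction with probability `directionConsistency` per tissue. Mean
#' expression is drawn log-normal per gene and split across tissues by a
#' Dirichlet profile.
#'
#' @param config a [simConfig()].
#' @return list with `panel` ([TissuePanel-class]), `sets`
#'   ([GeneSetCollection-class]) and `truth`: per-gene signal flags, the
#'   true per-tissue direction matrix, and a per-set data.frame (`set`,
#'   `planted`, `direction`).
#' @export
simulateDESummaries <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$nGenes))
    tissues <- sprintf("tissue%02d", seq_len(cfg$nTissues))
    affected <- if (identical(cfg$plantedTissues, "all"))
      seq_len(cfg$nTissues) else as.integer(cfg$plantedTissues)

    p <- matrix(runif(cfg$nGenes * cfg$nTissues), cfg$nGenes, cfg$nTissues,
                dimnames = list(genes, tissues))
    fc <- matrix(rnorm(cfg$nGenes * cfg$nTissues, 0, cfg$sigmaNullLfc),
                 cfg$nGenes, cfg$nTissues, dimnames = list(genes, tissues))
    true_dir <- matrix(0L, cfg$nGenes, cfg$nTissues,
                       dimnames = list(genes, tissues))

    # gene sets: planted sets first, from disjoint pools; null sets random
    sizes <- sample(seq(cfg$setSizeRange[1], cfg$setSizeRange[2]),
                    cfg$nSets, replace = TRUE)
    set_names <- sprintf("SET%03d", seq_len(cfg$nSets))
    sets <- vector("list", cfg$nSets)
    pool <- sample(cfg$nGenes)   # shuffled gene indices for disjoint planting
    used <- 0L
    planted <- seq_len(cfg$nPlanted)
    cons <- rep_len(cfg$directionConsistency, max(cfg$nPlanted, 1L))
    dirs <- rep(NA_integer_, cfg$nSets)
    for (s in seq_len(cfg$nSets)) {
      if (s %in% planted) {
        idx <- pool[(used + 1L):(used + sizes[s])]
        used <- used + sizes[s]
      } else {
        idx <- sample.int(cfg$nGenes, sizes[s])
      }
      sets[[s]] <- genes[idx]
      if (s %in% planted) {
        d <- if (identical(cfg$plantedDirection, "random"))
          sample(c(-1L, 1L), 1) else as.integer(cfg$plantedDirection)
        dirs[s] <- d
        for (t in affected) {
          p[idx, t] <- rbeta(length(idx), cfg$alpha, 1)
          flip <- runif(length(idx)) > cons[s]
          sgn <- ifelse(flip, -d, d)
          mag <- abs(rnorm(length(idx), cfg$meanAbsLfc, cfg$meanAbsLfc / 4))
          fc[idx, t] <- sgn * pmax(mag, 1e-6)
          true_dir[idx, t] <- sgn
        }
      }
    }
    names(sets) <- set_names

    total <- rlnorm(cfg$nGenes, cfg$exprMeanlog, cfg$exprSdlog)
    shares <- .rdirichlet1(cfg$nGenes, cfg$dirichletAlpha, cfg$nTissues)
    ex <- total * shares
    dimnames(ex) <- list(genes, tissues)

    signal_genes <- genes[sort(unique(unlist(
      lapply(planted, function(s) match(sets[[s]], genes)))))]
    panel <- TissuePanel(p = p, log2fc = fc, meanExpr = ex)
    truth <- list(
      signal = structure(genes %in% signal_genes, names = genes),
      direction = true_dir,
      sets = data.frame(set = set_names,
                        planted = seq_len(cfg$nSets) %in% planted,
                        direction = dirs, stringsAsFactors = FALSE),
      affected_tissues = tissues[affected])
    list(panel = panel, sets = GeneSetCollection(sets), truth = truth)
  })
}

#' Simulate a co-expression matrix with planted modules
#'
#' Latent-factor model: each module has one independent factor; member genes
#' are `loading * factor + sqrt(1 - loading^2) * noise`. Genes beyond the
#' module sizes are pure noise.
#'
#' @param nGenes,nSamples matrix dimensions (`nSamples >= 3`).
#' @param moduleSizes integer vector of module sizes (sum <= nGenes); empty
#'   for pure noise.
#' @param loading common factor loading in \[0, 1\].
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix) and `modules` (integer
#'   labels, 0 = noise).
#' @export
simulateCoexpression <- function(nGenes, nSamples, moduleSizes = integer(),
                                 loading = 0.9, seed = 1L) {
  if (nSamples < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(sum(moduleSizes) <= nGenes, loading >= 0, loading <= 1)
  withr::with_seed(as.integer(seed), {
    modules <- rep(0L, nGenes)
    if (length(moduleSizes))
      modules[seq_len(sum(moduleSizes))] <-
        rep(seq_along(moduleSizes), moduleSizes)
    expr <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
    if (length(moduleSizes)) {
      factors <- matrix(rnorm(length(moduleSizes) * nSamples),
                        length(moduleSizes), nSamples)
      for (m in seq_along(moduleSizes)) {
        rows <- which(modules == m)
        expr[rows, ] <- loading * matrix(factors[m, ], length(rows),
                                         nSamples, byrow = TRUE) +
          sqrt(1 - loading^2) * expr[rows, ]
      }
    }
    rownames(expr) <- sprintf("G%04d", seq_len(nGenes))
    colnames(expr) <- sprintf("S%03d", seq_len(nSamples))
    list(expr = expr, modules = modules)
  })
}

# Invert a unit-rate exponential draw through a piecewise-constant hazard:
# segments (start, end, hazard); returns the death age (possibly Inf).
.piecewise_death_age <- function(segments, e) {
  H <- 0
  for (r in seq_len(nrow(segments))) {
    len <- segments$end[r] - segments$start[r]
    h <- segments$hazard[r]
    if (e < H + h * len) return(segments$start[r] + (e - H) / h)
    H <- H + h * len
  }
  Inf
}

#' Simulate a cohort under status-specific constant hazards
#'
#' Exponential lifetimes under piecewise-constant hazards per status.
#' Individuals start in an initial status at `startAge` and may switch to
#' another status at a fixed age with a given probability; administrative
#' censoring applies at `censorAge`.
#'
#' @param nIndividuals cohort size.
#' @param hazardByStatus named numeric vector of annual hazards (> 0).
#' @param initialStatus character vector (recycled) of starting statuses.
#' @param statusChange optional list `list(at =, to =, prob =)`: switch to
#'   status `to` at age `at` with probability `prob`.
#' @param startAge age at entry (default 0).
#' @param censorAge administrative censoring age (default `Inf`; individuals
#'   alive then are censored).
#' @param seed integer seed.
#' @return A [CohortTable-class].
#' @export
simulateCohort <- function(nIndividuals, hazardByStatus,
                           initialStatus = names(hazardByStatus)[1],
                           statusChange = NULL, startAge = 0,
                           censorAge = Inf, seed = 1L) {
  if (any(hazardByStatus <= 0)) stop("hazards must be positive", call. = FALSE)
  if (is.null(names(hazardByStatus)))
    stop("hazardByStatus must be named by status", call. = FALSE)
  init <- rep_len(initialStatus, nIndividuals)
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", nIndividuals)
    for (i in seq_len(nIndividuals)) {
      st <- init[i]
      segs <- data.frame(start = startAge, end = Inf, status = st,
                         stringsAsFactors = FALSE)
      if (!is.null(statusChange) && runif(1) < statusChange$prob &&
          statusChange$at > startAge) {
        segs <- data.frame(start = c(startAge, statusChange$at),
                           end = c(statusChange$at, Inf),
                           status = c(st, statusChange$to),
                           stringsAsFactors = FALSE)
      }
      segs$hazard <- hazardByStatus[segs$status]
      death <- .piecewise_death_age(segs, rexp(1))
      terminal <- min(death, censorAge)
      event <- if (death <= censorAge) "death" else "censored"
      keep <- segs$start < terminal
      segs <- segs[keep, , drop = FALSE]
      segs$end <- pmin(segs$end, terminal)
      rows[[i]] <- data.frame(id = sprintf("ind%04d", i),
                              status = segs$status, start = segs$start,
                              end = segs$end, event = event,
                              event_age = terminal, stringsAsFactors = FALSE)
    }
    CohortTable(do.call(rbind, rows))
  })
}
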