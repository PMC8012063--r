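## Actuarial mortality rates: status-specific annual rates over fixed age
## intervals with exact person-years exposure accounting.

#' Status-specific exposure and annual mortality per age interval
#'
#' Subdivides the observation window into fixed-length age intervals and,
#' per (interval, status), accumulates deaths and person-years. An
#' individual alive through a whole interval contributes the full interval
#' length; one dying or censored mid-interval contributes time up to the
#' event; one switching status mid-interval contributes split exposure to
#' each status exactly at the transition age (so person-time is conserved).
#' The annual rate is deaths divided by person-years, already annualized
#' because exposure is in years.
#'
#' @param cohort a [CohortTable-class] (episodes validated: non-overlapping,
#'   contiguous, terminating at the event age).
#' @param intervalLength interval width in years (default 0.5).
#' @param window numeric length-2 observation window in years of age
#'   (default `c(1.5, 11.5)`).
#' @return data.frame with columns `interval`, `start`, `end`, `status`,
#'   `deaths`, `person_years`, `annual_rate` (NA when no exposure),
#'   `n_individuals`.
#' @export
statusExposure <- function(cohort, intervalLength = 0.5,
                           window = c(1.5, 11.5)) {
  tab <- cohortEpisodes(cohort)
  breaks <- seq(window[1], window[2], by = intervalLength)
  n_int <- length(breaks) - 1L
  statuses <- sort(unique(tab$status))
  py <- deaths <- matrix(0, n_int, length(statuses),
                         dimnames = list(NULL, statuses))
  # per (interval, status): set of ids with positive exposure
  ids_by_cell <- vector("list", n_int * length(statuses))
  dim(ids_by_cell) <- c(n_int, length(statuses))
  for (r in seq_len(nrow(tab))) {
    ep <- tab[r, ]
    s <- match(ep$status, statuses)
    for (k in seq_len(n_int)) {
      lo <- max(ep$start, breaks[k])
      hi <- min(ep$end, breaks[k + 1])
      if (hi <= lo) next
      py[k, s] <- py[k, s] + (hi - lo)
      ids_by_cell[[k, s]] <- c(ids_by_cell[[k, s]], ep$id)
      if (ep$event == "death" &&
          ep$event_age > breaks[k] && ep$event_age <= breaks[k + 1] &&
          abs(ep$end - ep$event_age) < 1e-9)
        deaths[k, s] <- deaths[k, s] + 1
    }
  }
  out <- expand.grid(interval = seq_len(n_int), status = statuses,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$start <- breaks[out$interval]
  out$end <- breaks[out$interval + 1L]
  out$deaths <- deaths[cbind(out$interval, match(out$status, statuses))]
  out$person_years <- py[cbind(out$interval, match(out$status, statuses))]
  out$annual_rate <- ifelse(out$person_years > 0,
                            out$deaths / out$person_years, NA_real_)
  out$n_individuals <- mapply(function(k, s)
    length(unique(ids_by_cell[[k, match(s, statuses)]])),
    out$interval, out$status)
  out[c("interval", "start", "end", "status", "deaths", "person_years",
        "annual_rate", "n_individuals")]
}

#' Filter sparse intervals and compare two statuses by paired t-test
#'
#' Drops (interval, status) rows observed in fewer than `minIndividuals`
#' individuals, then compares the annual rates of two named statuses across
#' their retained common intervals with a paired t-test. Normality of the
#' paired differences is reported via Shapiro-Wilk as a diagnostic only.
#'
#' @param table unfiltered output of [statusExposure()].
#' @param minIndividuals minimum individuals per (interval, status) row
#'   (default 10).
#' @param statusA,statusB the two statuses to compare (e.g. breeder vs
#'   non-breeder); omit to skip the comparison.
#' @return list with `table` (filtered) and `comparison` — either `NULL`, or
#'   a list with `statuses`, `n_intervals`, `mean_rate_a`, `mean_rate_b`,
#'   `t_p`, `shapiro_p`, or a `note` when fewer than 2 common intervals
#'   remain.
#' @export
mortalityRates <- function(table, minIndividuals = 10,
                           statusA = NULL, statusB = NULL) {
  keep <- table$n_individuals >= minIndividuals
  filtered <- table[keep, , drop = FALSE]
  comparison <- NULL
  if (!is.null(statusA) && !is.null(statusB)) {
    a <- filtered[filtered$status == statusA, ]
    b <- filtered[filtered$status == statusB, ]
    common <- intersect(a$interval, b$interval)
    ra <- a$annual_rate[match(common, a$interval)]
    rb <- b$annual_rate[match(common, b$interval)]
    ok <- !is.na(ra) & !is.na(rb)
    ra <- ra[ok]; rb <- rb[ok]
    if (length(ra) < 2) {
      comparison <- list(statuses = c(statusA, statusB),
                         n_intervals = length(ra),
                         note = "fewer than 2 common intervals; comparison undefined")
    } else {
      d <- ra - rb
      shap <- if (length(unique(d)) > 2 && length(d) >= 3 && sd(d) > 0)
        shapiro.test(d)$p.value else NA_real_
      tt <- t.test(ra, rb, paired = TRUE)
      comparison <- list(statuses = c(statusA, statusB),
                         n_intervals = length(ra),
                         mean_rate_a = mean(ra), mean_rate_b = mean(rb),
                         t_p = tt$p.value, shapiro_p = shap)
    }
  }
  list(table = filtered, comparison = comparison)
}
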