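#' One-way (tornado) sensitivity analysis
#'
#' Varies each model parameter individually between the `min` and `max` of its
#' table row, holding every other parameter at its base value, and records the
#' equilibrium third-line prevalence at both ends. Entries are returned sorted
#' by swing (absolute difference between the two ends), the order a tornado
#' diagram uses.
#'
#' @param params Base-case [gist_parameters()].
#' @param table Parameter table supplying the min--max ranges.
#' @return Object of class `gist_tornado`: a data frame with columns
#'   `parameter`, `low_outcome`, `high_outcome`, `swing` (all per-100,000
#'   third-line prevalence), sorted by decreasing swing.
#' @export
#' @examples
#' one_way_sa(gist_parameters())
one_way_sa <- function(params, table = default_parameter_table()) {
  stopifnot(inherits(params, "gist_parameters"))
  if (any(table$min > table$max)) stop("invalid range: min > max")
  eval_at <- function(name, value) {
    p <- unclass(params)
    p[[name]] <- value
    fit <- do.call(gist_parameters, p)
    state_outcomes(closed_form_equilibrium(fit), fit)$thirdline_prev_per_100k
  }
  res <- data.frame(parameter = table$name,
                    low_outcome = NA_real_, high_outcome = NA_real_)
  for (i in seq_len(nrow(table))) {
    res$low_outcome[i] <- eval_at(table$name[i], table$min[i])
    res$high_outcome[i] <- eval_at(table$name[i], table$max[i])
  }
  res$swing <- abs(res$high_outcome - res$low_outcome)
  res <- res[order(-res$swing), ]
  rownames(res) <- NULL
  structure(res, class = c("gist_tornado", "data.frame"))
}

#' @export
plot.gist_tornado <- function(x, base_outcome = NULL, ...) {
  d <- x[nrow(x):1, ]
  lo <- pmin(d$low_outcome, d$high_outcome)
  hi <- pmax(d$low_outcome, d$high_outcome)
  graphics::barplot(rep(0, nrow(d)), horiz = TRUE, xlim = range(0, hi * 1.05),
                    names.arg = d$parameter, las = 1, border = NA,
                    xlab = "Third-line prevalence per 100,000", ...)
  y <- seq(0.7, by = 1.2, length.out = nrow(d))
  graphics::rect(lo, y - 0.4, hi, y + 0.4, col = "steelblue", border = NA)
  if (!is.null(base_outcome)) graphics::abline(v = base_outcome, lty = 2)
  invisible(x)
}

# Draw n values for one parameter-table row, centred at `mean` with the row's
# SE and family. family == "fixed" or se == 0 returns the mean unchanged.
.draw_parameter <- function(n, mean, se, family) {
  if (family == "fixed" || se == 0) return(rep(mean, n))
  if (family == "beta") {
    ab <- beta_from_mean_se(mean, se)
    stats::rbeta(n, ab$alpha, ab$beta)
  } else {
    gp <- gamma_from_mean_se(mean, se)
    stats::rgamma(n, shape = gp$shape, scale = gp$scale)
  }
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets from the moment-matched PSA
#' distributions: gamma for the incidence, the transition rates and background
#' mortality; beta for the resectable proportion; `family = "fixed"` rows are
#' returned unchanged. Sampling means default to the table's base column but
#' can be recentred at the values in `params` (scenario analysis). Parameters
#' are drawn in table-row order so a fixed RNG state reproduces the draws
#' exactly.
#'
#' @param table Parameter table (base, se, family per row).
#' @param n Number of draws.
#' @param params Optional [gist_parameters()] whose values replace the table's
#'   base column as the sampling means.
#' @return Data frame with `n` rows, one column per parameter.
#' @export
sample_parameter_sets <- function(table = default_parameter_table(), n = 1,
                                  params = NULL) {
  means <- stats::setNames(table$base, table$name)
  if (!is.null(params)) {
    stopifnot(inherits(params, "gist_parameters"))
    means[table$name] <- unlist(unclass(params)[table$name])
  }
  out <- vector("list", nrow(table))
  names(out) <- table$name
  for (i in seq_len(nrow(table)))
    out[[i]] <- .draw_parameter(n, means[[i]], table$se[i], table$family[i])
  as.data.frame(out)
}

#' @rdname sample_parameter_sets
#' @param population Population denominator for the returned set.
#' @return `sample_parameter_set()` returns a single [gist_parameters()]
#'   object drawn with the current RNG state.
#' @export
sample_parameter_set <- function(table = default_parameter_table(),
                                 params = NULL,
                                 population = UK_POPULATION_2010) {
  draw <- sample_parameter_sets(table, 1, params)
  if (!is.null(params)) population <- params$population
  do.call(gist_parameters, c(as.list(draw), list(population = population)))
}

#' Probabilistic sensitivity analysis
#'
#' Samples all model parameters `n_draws` times from their moment-matched
#' distributions, solves the equilibrium for every draw, and summarizes the
#' outcome distribution: 95% credibility intervals as the 2.5th/97.5th
#' percentiles of the draws, and the probability that the third-line (and
#' total) prevalence lies below the ultra-orphan (2 per 100,000) and orphan
#' (50 per 100,000) thresholds.
#'
#' For scenario analysis, rows of `table` may be set to `family = "fixed"`
#' (pinning a parameter at its value in `params`) or left stochastic with the
#' sampling mean recentred at the scenario value (the default behaviour when
#' `params` differs from the table's base column).
#'
#' @param params [gist_parameters()] providing sampling means and population.
#' @param table Parameter table (SEs and families).
#' @param n_draws Number of draws (default 5,000).
#' @param seed RNG seed; results are bit-reproducible given `seed` and
#'   `n_draws`.
#' @return Object of class `gist_psa`: list with `draws` (data frame of
#'   sampled parameters and per-draw outcomes), `ci` (2.5/50/97.5 percentiles
#'   per outcome), `prob_below_ultra_orphan`, `prob_below_orphan`,
#'   `prob_total_below_orphan`, `n_draws`, `seed`.
#' @export
#' @examples
#' psa <- run_psa(n_draws = 200, seed = 42)
#' psa
run_psa <- function(params = gist_parameters(),
                    table = default_parameter_table(),
                    n_draws = 5000, seed = 1) {
  stopifnot(inherits(params, "gist_parameters"))
  if (n_draws < 1) stop("n_draws must be at least 1")
  set.seed(seed)
  d <- sample_parameter_sets(table, n_draws, params)
  z <- .equilibrium_counts(d$incidence, d$p_resectable, d$relapse_rate,
                           d$imatinib_failure_rate, d$sunitinib_failure_rate,
                           d$thirdline_exit_rate, d$background_mortality,
                           params$population)
  per100k <- 1e5 / params$population
  draws <- cbind(d, as.data.frame(z))
  draws$thirdline_count <- z[, "z5"]
  draws$total_count <- rowSums(z)
  draws$imatinib_count <- z[, "z3"]
  draws$sunitinib_count <- z[, "z4"]
  draws$thirdline_prev_per_100k <- draws$thirdline_count * per100k
  draws$total_prev_per_100k <- draws$total_count * per100k
  outcome_cols <- c("thirdline_prev_per_100k", "thirdline_count",
                    "total_prev_per_100k", "total_count", "imatinib_count",
                    "sunitinib_count")
  ci <- t(vapply(draws[outcome_cols], stats::quantile,
                 numeric(3), probs = c(0.025, 0.5, 0.975)))
  structure(list(draws = draws, ci = ci,
                 prob_below_ultra_orphan =
                   mean(draws$thirdline_prev_per_100k < ULTRA_ORPHAN_THRESHOLD),
                 prob_below_orphan =
                   mean(draws$thirdline_prev_per_100k < ORPHAN_THRESHOLD),
                 prob_total_below_orphan =
                   mean(draws$total_prev_per_100k < ORPHAN_THRESHOLD),
                 n_draws = n_draws, seed = seed),
            class = "gist_psa")
}

#' @export
print.gist_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws (seed",
      paste0(x$seed, ")\n"))
  ci <- x$ci
  fmt <- function(row) sprintf("%.2f (%.2f - %.2f)", ci[row, 2], ci[row, 1],
                               ci[row, 3])
  cat("  Third-line prevalence per 100,000:", fmt("thirdline_prev_per_100k"), "\n")
  cat("  Total prevalence per 100,000:     ", fmt("total_prev_per_100k"), "\n")
  cat(sprintf("  P(third-line prevalence < %g per 100,000) = %.1f%%\n",
              ULTRA_ORPHAN_THRESHOLD, 100 * x$prob_below_ultra_orphan))
  cat(sprintf("  P(third-line prevalence < %g per 100,000) = %.1f%%\n",
              ORPHAN_THRESHOLD, 100 * x$prob_below_orphan))
  invisible(x)
}
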