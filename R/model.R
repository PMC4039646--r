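#' Empty state vector
#'
#' Occupancy of the four living treatment states plus running totals of
#' cumulative incident cases and cumulative deaths. `z2` is post-resection
#' recurrence-free, `z3` on imatinib, `z4` on sunitinib, `z5` third-line
#' treatment-eligible.
#'
#' @return Named numeric vector `(z2, z3, z4, z5, cumulative_deaths,
#'   cumulative_incident)`, all zero.
#' @export
empty_state <- function() {
  c(z2 = 0, z3 = 0, z4 = 0, z5 = 0, cumulative_deaths = 0,
    cumulative_incident = 0)
}

# Per-state exit probabilities for one annual cycle.
# additive: disease and background exits converted separately and summed --
#   the default reading of parallel exit arrows. apportioned: one combined
#   exit probability 1 - exp(-(rate + mu)) split in proportion to the rates.
.exit_probs <- function(rate, mu, exits) {
  if (exits == "additive") {
    list(disease = rate_to_annual_prob(rate), death = rate_to_annual_prob(mu))
  } else {
    q <- rate_to_annual_prob(rate + mu)
    list(disease = q * rate / (rate + mu), death = q * mu / (rate + mu))
  }
}

#' One annual cycle of the difference equations
#'
#' Advances the open-population treatment-line chain by one year. New cases
#' `N = incidence * population` enter: a fraction `p_resectable` into the
#' post-resection state `z2`, the rest (metastatic/unresectable at diagnosis)
#' directly into the imatinib state `z3`. Each state loses occupants to its
#' disease transition (relapse, treatment failure, or third-line death) and to
#' background mortality, with per-year rates converted to annual probabilities
#' `1 - exp(-rate)`. Disease outflow from `z2`..`z4` feeds the next state;
#' disease outflow from `z5` is death. Mass is conserved exactly: incident
#' cases equal the change in total occupancy plus deaths.
#'
#' @param state Named state vector as from [empty_state()].
#' @param params A [gist_parameters()] object.
#' @param exits `"additive"` (default) treats disease and background exit
#'   probabilities as additive; `"apportioned"` splits a single combined exit
#'   probability in proportion to the rates.
#' @return The state vector after one year.
#' @export
#' @examples
#' annual_step(empty_state(), gist_parameters())
annual_step <- function(state, params, exits = c("additive", "apportioned")) {
  exits <- match.arg(exits)
  stopifnot(inherits(params, "gist_parameters"))
  n_new <- params$incidence * params$population
  rates <- c(params$relapse_rate, params$imatinib_failure_rate,
             params$sunitinib_failure_rate, params$thirdline_exit_rate)
  z <- state[c("z2", "z3", "z4", "z5")]
  disease_out <- death_out <- numeric(4)
  for (k in 1:4) {
    qs <- .exit_probs(rates[k], params$background_mortality, exits)
    if (qs$disease + qs$death > 1)
      stop("combined annual exit probability exceeds 1; use exits = \"apportioned\"")
    disease_out[k] <- z[k] * qs$disease
    death_out[k] <- z[k] * qs$death
  }
  inflow <- c(params$p_resectable * n_new,
              (1 - params$p_resectable) * n_new + disease_out[1],
              disease_out[2],
              disease_out[3])
  z_new <- z - disease_out - death_out + inflow
  deaths <- sum(death_out) + disease_out[4]
  c(z2 = unname(z_new[1]), z3 = unname(z_new[2]), z4 = unname(z_new[3]),
    z5 = unname(z_new[4]),
    cumulative_deaths = unname(state["cumulative_deaths"] + deaths),
    cumulative_incident = unname(state["cumulative_incident"] + n_new))
}

#' Closed-form equilibrium of the treatment-line chain
#'
#' Solves the fixed point of the annual difference equations sequentially:
#' each state's equilibrium occupancy is its annual inflow divided by its
#' total annual exit probability. Serves as the exact solution that the
#' iterated solver ([solve_equilibrium()]) must converge to.
#'
#' @inheritParams annual_step
#' @return Named numeric vector `(z2, z3, z4, z5)`.
#' @export
closed_form_equilibrium <- function(params, exits = c("additive", "apportioned")) {
  exits <- match.arg(exits)
  stopifnot(inherits(params, "gist_parameters"))
  n_new <- params$incidence * params$population
  rates <- c(params$relapse_rate, params$imatinib_failure_rate,
             params$sunitinib_failure_rate, params$thirdline_exit_rate)
  z <- numeric(4)
  inflow <- params$p_resectable * n_new
  for (k in 1:4) {
    qs <- .exit_probs(rates[k], params$background_mortality, exits)
    denom <- qs$disease + qs$death
    if (denom <= 0) stop("zero total exit probability in state ", k + 1)
    z[k] <- inflow / denom
    next_in <- z[k] * qs$disease
    inflow <- if (k == 1) (1 - params$p_resectable) * n_new + next_in else next_in
  }
  c(z2 = z[1], z3 = z[2], z4 = z[3], z5 = z[4])
}

#' Iterated equilibrium of the difference equations
#'
#' Runs [annual_step()] from the empty state until the largest yearly change
#' in any state occupancy is below `tolerance`. Convergence is geometric (the
#' update is a linear contraction), so the cap is generous.
#'
#' @inheritParams annual_step
#' @param tolerance Convergence tolerance in persons (max absolute yearly
#'   change).
#' @param max_iterations Iteration cap; non-convergence is flagged, never
#'   silent.
#' @return List of class `gist_equilibrium`: `state` (full state vector),
#'   `iterations`, `converged`, `residual`.
#' @export
#' @examples
#' solve_equilibrium(gist_parameters())$state
solve_equilibrium <- function(params, tolerance = 1e-6, max_iterations = 10000,
                              exits = c("additive", "apportioned")) {
  exits <- match.arg(exits)
  if (tolerance <= 0) stop("tolerance must be positive")
  state <- empty_state()
  occ <- c("z2", "z3", "z4", "z5")
  residual <- Inf
  it <- 0
  while (it < max_iterations) {
    nxt <- annual_step(state, params, exits)
    residual <- max(abs(nxt[occ] - state[occ]))
    state <- nxt
    it <- it + 1
    if (residual <= tolerance) break
  }
  converged <- residual <= tolerance
  if (!converged)
    warning("equilibrium not reached in ", max_iterations,
            " iterations (residual ", signif(residual, 3), " persons)")
  structure(list(state = state, iterations = it, converged = converged,
                 residual = residual),
            class = "gist_equilibrium")
}

#' @export
print.gist_equilibrium <- function(x, ...) {
  cat("Equilibrium of the GIST treatment-line chain\n")
  cat(sprintf("  iterations: %d  converged: %s  residual: %.3g persons\n",
              x$iterations, x$converged, x$residual))
  print(round(x$state[c("z2", "z3", "z4", "z5")], 1))
  invisible(x)
}

#' Prevalence thresholds
#'
#' `ULTRA_ORPHAN_THRESHOLD` (2 per 100,000; NICE, England and Wales) and
#' `ORPHAN_THRESHOLD` (50 per 100,000; EU).
#' @export
ULTRA_ORPHAN_THRESHOLD <- 2

#' @rdname ULTRA_ORPHAN_THRESHOLD
#' @export
ORPHAN_THRESHOLD <- 50

#' Outcome set for a model state
#'
#' Maps a state vector to the reported outcomes: absolute counts in the
#' imatinib, sunitinib and third-line states, the total living modeled GIST
#' population (`z2 + z3 + z4 + z5`), prevalences per 100,000 against the
#' population denominator, and the ultra-orphan indicator (third-line
#' prevalence below 2 per 100,000).
#'
#' @param state A state vector (or an object with `$state`).
#' @param params A [gist_parameters()] object (only `population` is used).
#' @return Named list with `thirdline_prev_per_100k`, `thirdline_count`,
#'   `total_prev_per_100k`, `total_count`, `imatinib_count`,
#'   `sunitinib_count`, `below_ultra_orphan`.
#' @export
state_outcomes <- function(state, params) {
  if (inherits(state, "gist_equilibrium")) state <- state$state
  z <- state[c("z2", "z3", "z4", "z5")]
  total <- sum(z)
  per100k <- 1e5 / params$population
  list(thirdline_prev_per_100k = unname(z["z5"]) * per100k,
       thirdline_count = unname(z["z5"]),
       total_prev_per_100k = total * per100k,
       total_count = total,
       imatinib_count = unname(z["z3"]),
       sunitinib_count = unname(z["z4"]),
       below_ultra_orphan = unname(z["z5"]) * per100k < ULTRA_ORPHAN_THRESHOLD)
}

#' Transient trajectory from an empty population
#'
#' Runs the annual difference equations for `years` cycles from the empty
#' state, e.g. to examine how quickly prevalence builds after a treatment
#' line is introduced.
#'
#' @inheritParams annual_step
#' @param years Number of annual cycles.
#' @return Data frame with columns `year`, `z2`, `z3`, `z4`, `z5`,
#'   `cumulative_deaths`, `cumulative_incident`.
#' @export
run_transient <- function(params, years, exits = c("additive", "apportioned")) {
  exits <- match.arg(exits)
  if (years < 1) stop("years must be at least 1")
  state <- empty_state()
  out <- matrix(NA_real_, nrow = years + 1, ncol = 6,
                dimnames = list(NULL, names(state)))
  out[1, ] <- state
  for (t in seq_len(years)) {
    state <- annual_step(state, params, exits)
    out[t + 1, ] <- state
  }
  data.frame(year = 0:years, out, row.names = NULL)
}

# Vectorized equilibrium third-line (and all-state) counts under the additive
# formulation; used by the PSA, tornado and threshold code where thousands of
# parameter sets are evaluated.
.equilibrium_counts <- function(incidence, p, g2, g3, g4, g5, mu, population) {
  n_new <- incidence * population
  qmu <- -expm1(-mu)
  z2 <- p * n_new / (-expm1(-g2) + qmu)
  z3 <- ((1 - p) * n_new + z2 * -expm1(-g2)) / (-expm1(-g3) + qmu)
  z4 <- z3 * -expm1(-g3) / (-expm1(-g4) + qmu)
  z5 <- z4 * -expm1(-g4) / (-expm1(-g5) + qmu)
  cbind(z2 = z2, z3 = z3, z4 = z4, z5 = z5)
}
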