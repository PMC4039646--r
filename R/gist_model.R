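#' Fit the open-population GIST prevalence model
#'
#' The central entry point of the package. Solves the open-population
#' treatment-line chain at the supplied parameters and returns a classed
#' object carrying the equilibrium state and the reported outcomes, with
#' `print`, `summary`, `coef`, `predict` (transient trajectory) and
#' `simulate` (probabilistic sensitivity draws) methods.
#'
#' @param params A [gist_parameters()] object; defaults to the base case.
#' @param method `"closed_form"` (exact sequential solution, default) or
#'   `"iterate"` (fixed-point iteration of the annual difference equations).
#' @param exits Exit-probability formulation, see [annual_step()].
#' @param ... Passed on to [solve_equilibrium()] when `method = "iterate"`.
#' @return Object of class `gist_model` with components `params`, `state`
#'   (equilibrium occupancies), `outcomes` (see [state_outcomes()]), `method`,
#'   `exits`, and for the iterated method `iterations`/`converged`/`residual`.
#' @export
#' @examples
#' fit <- gist_model()
#' fit
#' coef(fit)
#' summary(fit)
gist_model <- function(params = gist_parameters(),
                       method = c("closed_form", "iterate"),
                       exits = c("additive", "apportioned"), ...) {
  method <- match.arg(method)
  exits <- match.arg(exits)
  stopifnot(inherits(params, "gist_parameters"))
  fit <- list(params = params, method = method, exits = exits)
  if (method == "closed_form") {
    fit$state <- closed_form_equilibrium(params, exits)
  } else {
    eq <- solve_equilibrium(params, exits = exits, ...)
    fit$state <- eq$state[c("z2", "z3", "z4", "z5")]
    fit[c("iterations", "converged", "residual")] <-
      eq[c("iterations", "converged", "residual")]
  }
  fit$outcomes <- state_outcomes(fit$state, params)
  structure(fit, class = "gist_model")
}

#' @export
print.gist_model <- function(x, digits = 2, ...) {
  o <- x$outcomes
  cat("Open-population GIST prevalence model (equilibrium, ", x$method,
      ")\n", sep = "")
  cat(sprintf("  Third-line eligible: %s patients (%.*f per 100,000)\n",
              format(round(o$thirdline_count), big.mark = ","), digits,
              o$thirdline_prev_per_100k))
  cat(sprintf("  Total GIST population: %s patients (%.*f per 100,000)\n",
              format(round(o$total_count), big.mark = ","), digits,
              o$total_prev_per_100k))
  cat(sprintf("  Below ultra-orphan threshold (<%g per 100,000): %s\n",
              ULTRA_ORPHAN_THRESHOLD, o$below_ultra_orphan))
  invisible(x)
}

#' @export
coef.gist_model <- function(object, ...) {
  unlist(unclass(object$params))
}

#' @export
summary.gist_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.gist_model")
}

#' @export
print.summary.gist_model <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nState occupancies (persons):\n")
  print(round(fit$state, 1))
  cat("\nParameters:\n")
  print(fit$params)
  invisible(x)
}

#' Transient trajectory method
#'
#' `predict()` on a fitted model returns the year-by-year occupancies when the
#' population starts empty, over `years` annual cycles.
#'
#' @param object A `gist_model`.
#' @param years Number of annual cycles (default 50).
#' @param ... Unused.
#' @return Data frame as [run_transient()].
#' @export
predict.gist_model <- function(object, years = 50, ...) {
  run_transient(object$params, years, exits = object$exits)
}

#' Probabilistic sensitivity draws from a fitted model
#'
#' `simulate()` re-runs the model's PSA: `nsim` moment-matched parameter draws
#' with the equilibrium outcomes of each. A thin wrapper around [run_psa()].
#'
#' @param object A `gist_model`.
#' @param nsim Number of draws.
#' @param seed RNG seed (required for reproducibility).
#' @param table Parameter table supplying SEs and families.
#' @param ... Unused.
#' @return A `gist_psa` object; see [run_psa()].
#' @export
simulate.gist_model <- function(object, nsim = 5000, seed = 1,
                                table = default_parameter_table(), ...) {
  run_psa(params = object$params, table = table, n_draws = nsim, seed = seed)
}

#' @export
plot.gist_model <- function(x, years = 50, ...) {
  traj <- predict(x, years = years)
  per100k <- 1e5 / x$params$population
  graphics::matplot(traj$year, traj[, c("z2", "z3", "z4", "z5")] * per100k,
                    type = "l", lty = 1, lwd = 2,
                    xlab = "Years since empty population",
                    ylab = "Prevalence per 100,000", ...)
  graphics::legend("topleft", bty = "n", lty = 1, lwd = 2, col = 1:4,
                   legend = c("Post-resection", "Imatinib", "Sunitinib",
                              "Third-line eligible"))
  invisible(traj)
}
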