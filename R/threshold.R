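.thirdline_prev <- function(params) {
  state_outcomes(closed_form_equilibrium(params), params)$thirdline_prev_per_100k
}

.with_param <- function(params, name, value) {
  p <- unclass(params)
  p[[name]] <- value
  do.call(gist_parameters, p)
}

#' Threshold incidence for a target third-line prevalence
#'
#' Finds the GIST incidence at which the equilibrium third-line prevalence
#' reaches `target` per 100,000 with all other parameters held at their
#' values in `params`. Because every equilibrium count is exactly linear in
#' the incidence, the threshold is a single rescaling,
#' `incidence * target / prevalence(incidence)`; the result is verified by
#' re-evaluating the model at the returned value. A bisection fallback
#' ([threshold_by_bisection()]) is available and agrees to numerical
#' precision.
#'
#' @param params Base [gist_parameters()].
#' @param target Target third-line prevalence, per 100,000 (default the
#'   ultra-orphan boundary, 2).
#' @return Object of class `gist_threshold`: list with `parameter`,
#'   `threshold_value` (per person-year), `threshold_per_100k`,
#'   `target_prevalence`, `achieved_prevalence`.
#' @export
#' @examples
#' threshold_incidence(gist_parameters())
threshold_incidence <- function(params, target = ULTRA_ORPHAN_THRESHOLD) {
  stopifnot(inherits(params, "gist_parameters"))
  if (target <= 0) stop("target must be positive")
  base_prev <- .thirdline_prev(params)
  if (base_prev <= 0) stop("base-case third-line prevalence is zero")
  inc_star <- params$incidence * target / base_prev
  achieved <- .thirdline_prev(.with_param(params, "incidence", inc_star))
  structure(list(parameter = "incidence",
                 threshold_value = inc_star,
                 threshold_per_100k = inc_star * 1e5,
                 target_prevalence = target,
                 achieved_prevalence = achieved),
            class = "gist_threshold")
}

#' Threshold third-line exit rate for a target prevalence
#'
#' Bisects on the third-line exit rate until the equilibrium third-line
#' prevalence equals `target` per 100,000, all other parameters fixed.
#' Prevalence is continuous and strictly decreasing in the exit rate, so the
#' crossing is unique; prevalence exceeds the target for rates at or *below*
#' the returned value (a lower exit rate means longer third-line survival and
#' a larger standing population). The implied median survival
#' `log(2) / rate` is reported alongside.
#'
#' The initial bracket is widened automatically (up to the attainable range);
#' a target above the supremum attainable as the exit rate approaches zero is
#' an explicit error naming that supremum.
#'
#' @inheritParams threshold_incidence
#' @param bracket Initial search interval for the exit rate, per year.
#' @param tol Bisection tolerance on |prevalence - target|, per 100,000.
#' @return Object of class `gist_threshold` with `threshold_value` (per-year
#'   rate), `implied_median_years`, `target_prevalence`,
#'   `achieved_prevalence`, `bracket`.
#' @export
#' @examples
#' threshold_thirdline_rate(gist_parameters())
threshold_thirdline_rate <- function(params, target = ULTRA_ORPHAN_THRESHOLD,
                                     bracket = c(0.01, 5), tol = 1e-6) {
  stopifnot(inherits(params, "gist_parameters"))
  if (target <= 0) stop("target must be positive")
  prev_at <- function(g5) .thirdline_prev(.with_param(params, "thirdline_exit_rate", g5))
  lo <- bracket[1]; hi <- bracket[2]
  # prevalence decreases in the rate: need prev(lo) >= target >= prev(hi)
  while (prev_at(hi) > target && hi < 1e6) hi <- hi * 2
  while (prev_at(lo) < target && lo > 1e-12) lo <- lo / 2
  if (prev_at(lo) < target) {
    sup <- prev_at(1e-12)
    stop(sprintf(paste0("target %.4g per 100,000 is not attainable: ",
                        "prevalence approaches %.4g as the exit rate ",
                        "approaches zero"), target, sup))
  }
  if (prev_at(hi) > target)
    stop("target not attainable within any finite exit rate bracket")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- prev_at(mid)
    if (abs(pm - target) < tol) break
    if (pm > target) lo <- mid else hi <- mid
  }
  structure(list(parameter = "thirdline_exit_rate",
                 threshold_value = mid,
                 implied_median_years = rate_to_median(mid),
                 target_prevalence = target,
                 achieved_prevalence = prev_at(mid),
                 bracket = c(lo, hi)),
            class = "gist_threshold")
}

#' Bisection fallback for the incidence threshold
#'
#' Solves the same crossing as [threshold_incidence()] by bisection instead of
#' the linear rescaling; the two agree to numerical precision (prevalence is
#' strictly increasing in incidence).
#'
#' @inheritParams threshold_thirdline_rate
#' @return The threshold incidence, per person-year.
#' @export
threshold_by_bisection <- function(params, target = ULTRA_ORPHAN_THRESHOLD,
                                   bracket = c(1e-8, 1e-3), tol = 1e-12) {
  prev_at <- function(inc) .thirdline_prev(.with_param(params, "incidence", inc))
  lo <- bracket[1]; hi <- bracket[2]
  while (prev_at(hi) < target) hi <- hi * 2
  while (prev_at(lo) > target) lo <- lo / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- prev_at(mid)
    if (abs(pm - target) < tol) break
    if (pm < target) lo <- mid else hi <- mid
  }
  mid
}

#' @export
print.gist_threshold <- function(x, ...) {
  cat("Threshold analysis: third-line prevalence =", x$target_prevalence,
      "per 100,000\n")
  if (x$parameter == "incidence") {
    cat(sprintf("  Threshold incidence: %.3g per person-year (%.2f per 100,000 person-years)\n",
                x$threshold_value, x$threshold_per_100k))
    cat("  Prevalence exceeds the target for incidences at or above this value.\n")
  } else {
    cat(sprintf("  Threshold third-line exit rate: %.3f per year (median survival %.2f years)\n",
                x$threshold_value, x$implied_median_years))
    cat("  Prevalence exceeds the target for exit rates at or below this value,\n")
    cat("  i.e. for median third-line survival at or above",
        sprintf("%.2f years.\n", x$implied_median_years))
  }
  invisible(x)
}
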