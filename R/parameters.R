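#' Default model parameter table
#'
#' Returns the package's default parameter table for UK unresectable/metastatic
#' GIST: one row per model parameter with its base-case value, standard error,
#' the minimum--maximum range used for one-way sensitivity analysis, and the
#' distribution family used for probabilistic sensitivity analysis (PSA).
#' Rates are per year; the incidence is per person-year; the resectable
#' proportion is dimensionless.
#'
#' The seven parameters are: `incidence` (newly diagnosed GIST per person-year),
#' `p_resectable` (proportion resectable at diagnosis), `relapse_rate`
#' (post-resection relapse, per year), `imatinib_failure_rate` and
#' `sunitinib_failure_rate` (first/second-line treatment failure, per year),
#' `thirdline_exit_rate` (death after imatinib and sunitinib failure, per
#' year), and `background_mortality` (all-cause, per year).
#'
#' @return A data frame with columns `name`, `base`, `se`, `min`, `max`,
#'   `family` (one of `"gamma"`, `"beta"`, `"fixed"`).
#' @seealso [read_parameter_table()], [gist_parameters()]
#' @export
#' @examples
#' default_parameter_table()
default_parameter_table <- function() {
  path <- system.file("extdata", "gist_parameters.csv", package = "gistprev",
                      mustWork = TRUE)
  read_parameter_table(path)
}

#' Read or write a parameter table
#'
#' A parameter table is a CSV with header `name,base,se,min,max,family`; one
#' row per model parameter. [read_parameter_table()] validates every row (see
#' [validate_parameter_row()]).
#'
#' @param path Path to a CSV file.
#' @param table A parameter table data frame.
#' @return `read_parameter_table()` returns the validated data frame;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "base", "se", "min", "max", "family")
  if (!all(required %in% names(tab)))
    stop("parameter table must have columns: ", paste(required, collapse = ", "))
  tab <- tab[required]
  for (i in seq_len(nrow(tab))) validate_parameter_row(tab[i, ])
  if (anyDuplicated(tab$name)) stop("duplicated parameter names")
  tab
}

#' @rdname read_parameter_table
#' @export
write_parameter_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate one parameter-table row
#'
#' Enforces the invariants of a model parameter: `min <= base <= max`,
#' `se >= 0`; a beta-family parameter must be a proportion with
#' `se^2 < base * (1 - base)`; a gamma-family parameter with positive `se`
#' must have `base > 0`.
#'
#' @param row A one-row data frame with columns `name`, `base`, `se`, `min`,
#'   `max`, `family`.
#' @return The row, invisibly; errors if invalid.
#' @export
validate_parameter_row <- function(row) {
  nm <- as.character(row$name)
  if (!row$family %in% c("gamma", "beta", "fixed"))
    stop(nm, ": family must be gamma, beta or fixed")
  if (is.na(row$base) || is.na(row$se)) stop(nm, ": base and se must be given")
  if (row$se < 0) stop(nm, ": se must be nonnegative")
  if (row$min > row$base || row$base > row$max)
    stop(nm, ": must have min <= base <= max")
  if (row$family == "beta") {
    if (row$base < 0 || row$base > 1) stop(nm, ": beta family requires base in [0, 1]")
    if (row$se > 0 && row$se^2 >= row$base * (1 - row$base))
      stop(nm, ": beta family requires se^2 < base * (1 - base)")
  }
  if (row$family == "gamma" && row$se > 0 && row$base <= 0)
    stop(nm, ": gamma family requires base > 0")
  invisible(row)
}

#' UK population denominator (mid-2010)
#'
#' The open-population size the model uses by default.
#' @export
UK_POPULATION_2010 <- 62262100

#' Construct a model parameter set
#'
#' Bundles the seven model parameters and the population denominator into a
#' validated `gist_parameters` object, the single input every model function
#' consumes. Defaults are the base-case column of [default_parameter_table()]
#' and the 2010 UK population.
#'
#' @param incidence GIST incidence, per person-year.
#' @param p_resectable Proportion of incident cases resectable at diagnosis.
#' @param relapse_rate Post-resection relapse rate, per year.
#' @param imatinib_failure_rate First-line (imatinib) failure rate, per year.
#' @param sunitinib_failure_rate Second-line (sunitinib) failure rate, per year.
#' @param thirdline_exit_rate Third-line exit (death) rate, per year.
#' @param background_mortality All-cause background mortality rate, per year.
#' @param population Open-population size (person count).
#' @return An object of class `gist_parameters`: a named list of the eight
#'   values above.
#' @export
#' @examples
#' gist_parameters()
#' gist_parameters(incidence = 1.5e-5)
gist_parameters <- function(incidence = 1.053e-5,
                            p_resectable = 0.8,
                            relapse_rate = 0.0464,
                            imatinib_failure_rate = 0.351,
                            sunitinib_failure_rate = 0.974,
                            thirdline_exit_rate = 0.904,
                            background_mortality = 0.0314,
                            population = UK_POPULATION_2010) {
  p <- list(incidence = incidence,
            p_resectable = p_resectable,
            relapse_rate = relapse_rate,
            imatinib_failure_rate = imatinib_failure_rate,
            sunitinib_failure_rate = sunitinib_failure_rate,
            thirdline_exit_rate = thirdline_exit_rate,
            background_mortality = background_mortality,
            population = population)
  validate_gist_parameters(p)
  structure(p, class = "gist_parameters")
}

validate_gist_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all parameters must be finite numeric scalars")
  rates <- c("incidence", "relapse_rate", "imatinib_failure_rate",
             "sunitinib_failure_rate", "thirdline_exit_rate",
             "background_mortality")
  if (any(unlist(p[rates]) <= 0))
    stop("incidence and all rates must be strictly positive")
  if (p$p_resectable <= 0 || p$p_resectable >= 1)
    stop("p_resectable must lie strictly between 0 and 1")
  if (p$population <= 0) stop("population must be positive")
  invisible(p)
}

#' @export
print.gist_parameters <- function(x, ...) {
  cat("GIST prevalence model parameters\n")
  lab <- c(incidence = "Incidence (per person-year)",
           p_resectable = "Proportion resectable",
           relapse_rate = "Post-resection relapse rate (/yr)",
           imatinib_failure_rate = "Imatinib failure rate (/yr)",
           sunitinib_failure_rate = "Sunitinib failure rate (/yr)",
           thirdline_exit_rate = "Third-line exit rate (/yr)",
           background_mortality = "Background mortality rate (/yr)",
           population = "Population")
  for (nm in names(lab))
    cat(sprintf("  %-36s %s\n", lab[[nm]], format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Build a parameter set from a parameter table
#'
#' Takes the `base` column of a parameter table (plus a population size) and
#' returns the corresponding [gist_parameters()] object. `overrides` replaces
#' named base values first, so scenario definitions can be applied to the
#' default table in one call.
#'
#' @param table A parameter table (see [default_parameter_table()]).
#' @param population Population denominator.
#' @param overrides Named list of parameter values replacing table base values.
#' @return A `gist_parameters` object.
#' @export
parameter_set_from_table <- function(table = default_parameter_table(),
                                     population = UK_POPULATION_2010,
                                     overrides = list()) {
  base <- stats::setNames(as.list(table$base), table$name)
  bad <- setdiff(names(overrides), c(names(base), "population"))
  if (length(bad)) stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
  base[names(overrides)] <- overrides
  if (!is.null(overrides$population)) population <- overrides$population
  base$population <- population
  do.call(gist_parameters, base)
}

# ---- unit conversions -------------------------------------------------------

#' Convert between median time-to-event and exponential rate
#'
#' Under the exponential time-to-event assumption used throughout the model,
#' a median survival of `m` years corresponds to a constant annual rate
#' `log(2) / m`, and conversely. The two functions are mutual inverses.
#'
#' @param median_years Median time to event, in years (positive).
#' @param rate Event rate, per year (positive).
#' @return A rate (per year) or a median (years).
#' @export
#' @examples
#' median_to_rate(2)        # 0.347 per year
#' rate_to_median(0.904)    # 0.77 years
median_to_rate <- function(median_years) {
  if (any(!is.finite(median_years)) || any(median_years <= 0))
    stop("median_years must be positive and finite")
  log(2) / median_years
}

#' @rdname median_to_rate
#' @export
rate_to_median <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("rate must be positive and finite")
  log(2) / rate
}

#' Convert an annual rate to an annual probability
#'
#' `1 - exp(-rate)`: the probability that at least one event occurs within a
#' one-year cycle at constant rate `rate`. Keeping the difference equations in
#' probabilities (rather than raw rates) keeps every state update stable even
#' when competing rates sum above 1, as they do for the sunitinib state.
#'
#' @param rate Nonnegative rate, per year.
#' @return Probability in `[0, 1)`; strictly increasing in `rate`.
#' @export
#' @examples
#' rate_to_annual_prob(log(2))  # 0.5: one median per year
rate_to_annual_prob <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be nonnegative and finite")
  -expm1(-rate)
}

# ---- moment matching for PSA distributions ---------------------------------

#' Moment-matched gamma distribution
#'
#' Shape/scale of the gamma distribution with the given mean and standard
#' deviation: `shape = (mean/se)^2`, `scale = se^2/mean`. This is the standard
#' health-economics parameterization of rate uncertainty from a point estimate
#' and its standard error.
#'
#' @param mean Positive mean.
#' @param se Positive standard error (the target standard deviation).
#' @return Named list with `shape` and `scale`.
#' @export
#' @examples
#' gamma_from_mean_se(0.351, 0.103)
gamma_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Moment-matched beta distribution
#'
#' Alpha/beta of the beta distribution with the given mean and standard
#' deviation: with `nu = mean (1 - mean) / se^2 - 1`, `alpha = mean * nu` and
#' `beta = (1 - mean) * nu`. Used for the resectable proportion, whose support
#' must stay in (0, 1).
#'
#' @param mean Mean in (0, 1).
#' @param se Positive standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @return Named list with `alpha` and `beta`.
#' @export
#' @examples
#' beta_from_mean_se(0.8, 0.05)
beta_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("mean must lie strictly between 0 and 1")
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0) stop("se too large for mean: need se^2 < mean * (1 - mean)")
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

# ---- registry standardization and life-table weighting ---------------------

#' Direct-standardized incidence rate
#'
#' Applies stratum-specific incidence rates (cases / person-years) to a
#' reference population's stratum weights: the direct-standardized rate
#' `sum(rate_i * ref_i) / sum(ref_i)`. This is how age/sex-stratified registry
#' counts are projected onto a national population.
#'
#' @param strata Data frame with columns `cases`, `person_years`,
#'   `reference_population` (an `age_band`/`sex` label pair is carried but not
#'   used in the arithmetic).
#' @return The standardized rate, per person-year.
#' @export
standardize_incidence <- function(strata) {
  if (!is.data.frame(strata) || nrow(strata) == 0)
    stop("strata must be a non-empty data frame")
  req <- c("cases", "person_years", "reference_population")
  if (!all(req %in% names(strata)))
    stop("strata must have columns: ", paste(req, collapse = ", "))
  if (any(strata$person_years <= 0)) stop("person_years must be positive")
  if (any(strata$cases < 0) || any(strata$reference_population < 0))
    stop("cases and reference_population must be nonnegative")
  tot <- sum(strata$reference_population)
  if (tot <= 0) stop("reference populations must sum to a positive total")
  sum(strata$cases / strata$person_years * strata$reference_population) / tot
}

#' Patient-weighted background mortality rate
#'
#' Converts each age band's annual mortality probability to a rate
#' (`-log(1 - q)`) and averages the rates under the patient age-distribution
#' weights. Weighting on the rate scale composes correctly with the
#' disease-exit rates the model adds it to.
#'
#' @param life_table Data frame with columns `annual_mortality` (probability
#'   in `[0, 1)`) and `patient_weight` (nonnegative; normalized internally).
#' @return Weighted mortality rate, per year.
#' @export
weighted_background_mortality <- function(life_table) {
  if (!is.data.frame(life_table) || nrow(life_table) == 0)
    stop("life_table must be a non-empty data frame")
  req <- c("annual_mortality", "patient_weight")
  if (!all(req %in% names(life_table)))
    stop("life_table must have columns: ", paste(req, collapse = ", "))
  q <- life_table$annual_mortality
  w <- life_table$patient_weight
  if (any(q < 0) || any(q >= 1))
    stop("annual_mortality must lie in [0, 1); a probability of 1 implies an infinite rate")
  if (any(w < 0) || sum(w) <= 0) stop("patient weights must be nonnegative with positive sum")
  w <- w / sum(w)
  sum(w * (-log1p(-q)))
}
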