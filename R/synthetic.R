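#' Configuration for the synthetic fixture generators
#'
#' The generators emulate the aggregate inputs the real analysis consumes but
#' does not ship: registry-style age/sex-stratified incidence counts (Poisson
#' counts over person-years) and an age-banded life table with a GIST-like
#' patient age distribution. Defaults mirror the study conditions: nine
#' 10-year age bands, an overall incidence of 1.053 per 100,000 person-years,
#' and a mortality/incidence age gradient typical of a rare adult solid
#' tumour.
#'
#' @param seed RNG seed; every generator is deterministic given the config.
#' @param n_age_bands Number of 10-year age bands.
#' @param true_overall_incidence Target direct-standardized incidence, per
#'   person-year.
#' @param person_years_per_stratum Exposure per age/sex stratum.
#' @param incidence_gradient Log-linear increase in stratum incidence per age
#'   band (registry incidence of GIST rises with age).
#' @param mortality_gradient Log-linear increase in annual mortality per age
#'   band.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_age_bands = 9,
                             true_overall_incidence = 1.053e-5,
                             person_years_per_stratum = 2e6,
                             incidence_gradient = 0.35,
                             mortality_gradient = 0.65) {
  if (n_age_bands < 1) stop("n_age_bands must be at least 1")
  if (true_overall_incidence <= 0) stop("true_overall_incidence must be positive")
  if (person_years_per_stratum <= 0) stop("person_years_per_stratum must be positive")
  structure(list(seed = seed, n_age_bands = n_age_bands,
                 true_overall_incidence = true_overall_incidence,
                 person_years_per_stratum = person_years_per_stratum,
                 incidence_gradient = incidence_gradient,
                 mortality_gradient = mortality_gradient),
            class = "synthetic_config")
}

.age_band_labels <- function(n) {
  lo <- (seq_len(n) - 1) * 10
  c(paste0(lo[-n], "-", lo[-n] + 9), paste0(lo[n], "+"))
}

# Reference-population age weights: a plausibly ageing national population,
# mass declining in the oldest bands.
.reference_weights <- function(n) {
  w <- exp(-0.5 * ((seq_len(n) - 0.45 * n) / (0.45 * n))^2)
  w / sum(w)
}

#' Generate synthetic stratified incidence counts
#'
#' Poisson case counts per age-by-sex stratum over fixed person-years, with
#' stratum rates rising log-linearly with age and calibrated so that the
#' direct-standardized rate ([standardize_incidence()]) has expectation
#' `true_overall_incidence`. Reference-population weights are included, so the
#' output is directly consumable by the standardization step.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with columns `age_band`, `sex`, `cases`,
#'   `person_years`, `reference_population`.
#' @export
#' @examples
#' strata <- generate_incidence_strata(synthetic_config(seed = 7))
#' standardize_incidence(strata)
generate_incidence_strata <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_age_bands
  band <- .age_band_labels(n)
  relative <- exp(cfg$incidence_gradient * (seq_len(n) - 1))
  ref_w <- .reference_weights(n)
  # calibrate so the reference-weighted mean of stratum rates hits the target
  rates <- relative * cfg$true_overall_incidence / sum(ref_w * relative)
  out <- expand.grid(age_band = band, sex = c("F", "M"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$person_years <- cfg$person_years_per_stratum
  out$rate_true <- rates[match(out$age_band, band)]
  out$cases <- stats::rpois(nrow(out), out$rate_true * out$person_years)
  # both sexes share a band's reference weight equally
  out$reference_population <- 1e6 * ref_w[match(out$age_band, band)] / 2
  out$rate_true <- NULL
  out[c("age_band", "sex", "cases", "person_years", "reference_population")]
}

#' Generate a synthetic age-banded life table with patient weights
#'
#' Annual mortality probabilities rising log-linearly with age (Gompertz-like)
#' and a patient age distribution skewed toward older bands, calibrated so the
#' patient-weighted background mortality rate
#' ([weighted_background_mortality()]) equals 0.0314 per year in expectation;
#' seed-dependent jitter on the weights leaves it within the plausible UK
#' range (0.0269--0.0359).
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with columns `age_band`, `annual_mortality`,
#'   `patient_weight` (weights sum to 1).
#' @export
#' @examples
#' lt <- generate_life_table(synthetic_config(seed = 7))
#' weighted_background_mortality(lt)
generate_life_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_age_bands
  idx <- seq_len(n) - 1
  hazard <- 3e-4 * exp(cfg$mortality_gradient * idx)
  q <- -expm1(-hazard)
  # patient age distribution: older-skewed, like registry GIST cases
  w <- exp(0.45 * idx)
  w <- w * exp(stats::rnorm(n, 0, 0.05))
  w <- w / sum(w)
  # rescale weights along the age axis so the weighted rate hits the target
  target <- 0.0314
  shift <- function(s) {
    ws <- w * exp(s * idx)
    ws <- ws / sum(ws)
    sum(ws * hazard) - target
  }
  s <- stats::uniroot(shift, c(-2, 2), tol = 1e-12)$root
  w <- w * exp(s * idx)
  w <- w / sum(w)
  data.frame(age_band = .age_band_labels(n), annual_mortality = q,
             patient_weight = w)
}

#' Random valid parameter set
#'
#' Draws each model parameter uniformly within its table min--max range;
#' always satisfies the [gist_parameters()] invariants. Used as the fixture
#' for property tests over the valid parameter space.
#'
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param table Parameter table supplying the ranges.
#' @param population Population denominator.
#' @return A [gist_parameters()] object.
#' @export
random_parameter_set <- function(seed = NULL,
                                 table = default_parameter_table(),
                                 population = UK_POPULATION_2010) {
  if (!is.null(seed)) set.seed(seed)
  vals <- stats::setNames(
    stats::runif(nrow(table), table$min, table$max), table$name)
  do.call(gist_parameters, c(as.list(vals), list(population = population)))
}
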