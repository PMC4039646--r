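# Shared fixtures for the test suite.

base_params <- function() gist_parameters()

# Printed study results the deterministic formulation is checked against.
published <- list(
  thirdline_count = 598, total_count = 9365, imatinib_count = 1422,
  sunitinib_count = 599, total_prev = 15.04, thirdline_prev = 0.96,
  scenario2_thirdline = 954,
  prob_base = 99.9, prob_sc1 = 99.6, prob_sc2 = 90.6, prob_sc3 = 37.9,
  threshold_incidence_per_100k = 2.2, threshold_median_years = 2.2
)

occ <- c("z2", "z3", "z4", "z5")
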