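Package: gistprev
Title: Open-Population Prevalence Model for GIST at Successive Treatment Lines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the prevalence and absolute number of patients with
    unresectable or metastatic gastrointestinal stromal tumour (GIST) on
    first-line (imatinib), second-line (sunitinib) and third-line treatment in
    an open population, using an annual-cycle multi-state difference-equation
    model with continuous inflow of newly diagnosed cases. Provides the
    equilibrium and transient solutions of the treatment-line chain, one-way
    (tornado) and probabilistic sensitivity analyses with moment-matched gamma
    and beta parameter distributions, threshold analysis against orphan and
    ultra-orphan prevalence boundaries, scenario reporting, and synthetic
    registry-style fixtures (stratified incidence counts and life tables) for
    testing the standardization and mortality-weighting steps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
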