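Package: graftflow
Title: Predictive Haemodynamics of Coronary Bypass Graft Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-dimensional pulse-wave simulation of patient-specific coronary
    circulations coupled to lumped-parameter (0D) stenosis and Windkessel
    outflow models, for planning total-arterial coronary bypass grafting.
    Builds the twelve composite, sequential and jump graft topologies used in
    total arterial revascularisation on any coronary network, solves each for
    periodic blood flow and pressure with a Richtmyer two-step Lax-Wendroff
    scheme, and derives the functional metrics surgeons use intraoperatively:
    instantaneous wave-free ratio (iFR) and derived fractional flow reserve
    per stenosed vessel, transit-time flowmetry indices (mean graft flow,
    pulsatility index, diastolic filling, backward flow) per graft, and
    regional myocardial perfusion. Grafting plans are classified as
    unsatisfactory, satisfactory or ideal, cohorts summarised, and the
    associated contingency-table statistics computed. Synthetic five-patient
    triple-vessel-disease archetypes make the whole pipeline runnable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
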