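# Shared helpers: run the analysis stages on a simulated dataset without
# touching disk.

traits_from_sim <- function(sim) {
  suppressWarnings(community_traits(sim$survey, elevations = sim$soil))
}

strategy_from_sim <- function(sim, alpha = 0.05) {
  tr <- traits_from_sim(sim)
  rs <- resorption_table(tr, sim$litter, mlcf = sim$truth$config$mlcf,
                         survey = sim$survey)
  control_strategy(tr$ratio_NP[match(rs$plot_id, tr$plot_id)],
                   rs$resorbed_NP, alpha = alpha)
}

homeostasis_np_from_sim <- function(sim, alpha = 0.05) {
  tr <- traits_from_sim(sim)
  m <- match(tr$plot_id, sim$soil$plot_id)
  fit_homeostasis(sim$soil$TN[m] / sim$soil$TP[m], tr$ratio_NP,
                  alpha = alpha, trait = "N:P")
}

# Tiny well-formed dataset used by IO/validation tests.
tiny_dataset <- function() {
  survey <- data.frame(
    plot_id = c("P1", "P1", "P2"),
    species = c("spA", "spB", "spA"),
    biomass = c(10, 30, 5),
    leaf_C = c(440, 450, 445),
    leaf_N = c(24, 26, 25),
    leaf_P = c(1.0, 2.0, 1.8),
    stringsAsFactors = FALSE)
  litter <- data.frame(
    plot_id = c("P1", "P2"),
    species = rep(pooled_token(), 2),
    senesced_N = c(6, 7),
    senesced_P = c(0.5, 0.6),
    stringsAsFactors = FALSE)
  soil <- data.frame(
    plot_id = c("P1", "P2"),
    elevation = c(2000, 2500),
    TN = c(0.8, 1.1),
    TP = c(0.6, 0.7),
    stringsAsFactors = FALSE)
  list(survey = survey, litter = litter, soil = soil)
}
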