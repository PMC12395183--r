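# Deterministic per-table sub-seed so adding draws to one table never
# perturbs another table's stream.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2017L + stage * 10007L
}

#' Configuration for the synthetic-community generator
#'
#' Bundles and validates every knob of [generate_dataset()]. Defaults emulate
#' a 6-site x 4-plot survey on an arid-mountain elevational gradient
#' (1960-3548 m): montane semi-shrub desert at the two lowest sites
#' (species-level litter) grading into steppe above (pooled litter);
#' green-leaf C ~ 445 g/kg and N ~ 25 g/kg at the lowest site with leaf N
#' rising ~1.5 g/kg per km; community leaf N:P centred near 13.3 (inside the
#' 10-20 co-limitation band) and tied to soil N:P through a homeostasis
#' coefficient `H_true = 16.34`; resorbed N:P following the power law
#' `omega_true * (N:P)^lambda_true` with `lambda_true = 0.912` and
#' `omega_true = 1.33`; and N resorption efficiency ~ Normal(78, 4) percent,
#' which together imply P resorption efficiencies in the low-to-mid 70s.
#'
#' @param seed Integer master seed; each output table draws from its own
#'   deterministic sub-stream.
#' @param n_sites,plots_per_site Survey design (defaults 6 and 4).
#' @param species_range Integer range of species per plot (default 4-8).
#' @param elevations Site elevations in m, strictly increasing; default
#'   evenly spaced over 1960-3548.
#' @param lambda_true,omega_true Power-law exponent and coefficient linking
#'   resorbed N:P to green-leaf N:P.
#' @param H_true,np_constant Homeostasis coefficient and multiplier `c` in
#'   `leaf N:P = c * (soil N:P)^(1/H)`.
#' @param nre_mean,nre_sd Mean and sd of plot N resorption efficiency (%).
#' @param green_means Named vector `c(C=, N=, P=)`: green-leaf trait means
#'   (g/kg) at the lowest site. `P` is a fallback only; leaf P is normally
#'   derived from leaf N and the homeostasis-driven N:P target.
#' @param elevation_slopes Named vector `c(C=, N=, P=)`: linear trend in site
#'   trait means per km of elevation.
#' @param trait_sigma Lognormal sd of species traits about the site mean.
#' @param np_sigma Lognormal sd of plot leaf N:P about the homeostasis curve.
#' @param resorption_sigma Lognormal sd of the resorbed N:P ratio about the
#'   power law.
#' @param litter_sigma Lognormal sd of species-level senesced concentrations
#'   about the plot value (shrub plots only).
#' @param soil_np_mean,soil_np_sigma Median and lognormal sd of soil TN:TP.
#' @param soil_tn_base,soil_tn_slope Soil TN (g/kg) at the lowest site and
#'   its trend per km.
#' @param soil_sigma Lognormal sd of plot soil TN about the site mean.
#' @param biomass_base,biomass_slope Plot total biomass (g/m2) at the lowest
#'   site and trend per km.
#' @param shrub_sites Indices of sites whose litter is written species-level;
#'   all other sites get one pooled row per plot.
#' @param mlcf Mass loss correction factor used in the back-solve.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_sites = 6L,
                              plots_per_site = 4L,
                              species_range = c(4L, 8L),
                              elevations = seq(1960, 3548, length.out = n_sites),
                              lambda_true = 0.912,
                              omega_true = 1.33,
                              H_true = 16.34,
                              np_constant = 13.3,
                              nre_mean = 78,
                              nre_sd = 4,
                              green_means = c(C = 445, N = 25, P = 1.9),
                              elevation_slopes = c(C = 0, N = 1.5, P = 0),
                              trait_sigma = 0.08,
                              np_sigma = 0.05,
                              resorption_sigma = 0.05,
                              litter_sigma = 0.10,
                              soil_np_mean = 1.33,
                              soil_np_sigma = 0.8,
                              soil_tn_base = 0.5,
                              soil_tn_slope = 0.4,
                              soil_sigma = 0.15,
                              biomass_base = 80,
                              biomass_slope = 40,
                              shrub_sites = 1:2,
                              mlcf = 0.762) {
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              plots_per_site = as.integer(plots_per_site),
              species_range = as.integer(species_range),
              elevations = elevations, lambda_true = lambda_true,
              omega_true = omega_true, H_true = H_true,
              np_constant = np_constant, nre_mean = nre_mean, nre_sd = nre_sd,
              green_means = green_means, elevation_slopes = elevation_slopes,
              trait_sigma = trait_sigma, np_sigma = np_sigma,
              resorption_sigma = resorption_sigma, litter_sigma = litter_sigma,
              soil_np_mean = soil_np_mean, soil_np_sigma = soil_np_sigma,
              soil_tn_base = soil_tn_base, soil_tn_slope = soil_tn_slope,
              soil_sigma = soil_sigma, biomass_base = biomass_base,
              biomass_slope = biomass_slope, shrub_sites = shrub_sites,
              mlcf = mlcf)
  sig <- c(cfg$trait_sigma, cfg$np_sigma, cfg$resorption_sigma,
           cfg$litter_sigma, cfg$soil_np_sigma, cfg$soil_sigma, cfg$nre_sd)
  if (any(sig < 0)) stop("all sigma parameters must be >= 0", call. = FALSE)
  if (length(cfg$elevations) != cfg$n_sites)
    stop("elevations must have length n_sites", call. = FALSE)
  if (is.unsorted(cfg$elevations, strictly = TRUE))
    stop("elevations must be strictly increasing", call. = FALSE)
  if (cfg$nre_mean <= 0 || cfg$nre_mean >= 100)
    stop("nre_mean must lie in (0, 100)", call. = FALSE)
  if (cfg$mlcf <= 0 || cfg$mlcf > 1) stop("mlcf must lie in (0, 1]", call. = FALSE)
  if (cfg$H_true <= 0 || cfg$omega_true <= 0 || cfg$np_constant <= 0)
    stop("H_true, omega_true and np_constant must be positive", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d sites x %d plots, elevations %g-%g m\n",
              x$n_sites, x$plots_per_site, min(x$elevations), max(x$elevations)))
  cat(sprintf("  lambda = %g, omega = %g, H = %g, NRE ~ N(%g, %g)\n",
              x$lambda_true, x$omega_true, x$H_true, x$nre_mean, x$nre_sd))
  invisible(x)
}

#' Back-solve senesced-leaf concentrations from resorption targets
#'
#' Inverts the resorption equations: given green-leaf community N and P, a
#' target N resorption efficiency and a target resorbed N:P ratio, returns
#' the senesced concentrations that reproduce those targets exactly under the
#' given mass loss correction factor:
#' `LTN_s = LTN * (1 - nre/100) / mlcf` and
#' `LTP_s = (LTP - (LTN - LTN_s * mlcf) / resorbed_np_target) / mlcf`.
#'
#' @param LTN,LTP Green-leaf community N and P (g/kg), positive.
#' @param nre_target Target N resorption efficiency in percent, in (0, 100).
#' @param resorbed_np_target Target resorbed N:P ratio, positive.
#' @param mlcf Mass loss correction factor in (0, 1].
#' @return Named numeric vector `c(LTN_s =, LTP_s =)`.
#' @export
backsolve_senesced <- function(LTN, LTP, nre_target, resorbed_np_target,
                               mlcf = 0.762) {
  if (LTN <= 0 || LTP <= 0) stop("LTN and LTP must be positive", call. = FALSE)
  if (nre_target <= 0 || nre_target >= 100)
    stop("nre_target must lie strictly between 0 and 100", call. = FALSE)
  if (resorbed_np_target <= 0)
    stop("resorbed_np_target must be positive", call. = FALSE)
  ltn_s <- LTN * (1 - nre_target / 100) / mlcf
  resorbed_n <- LTN - ltn_s * mlcf        # = LTN * nre/100
  ltp_s <- (LTP - resorbed_n / resorbed_np_target) / mlcf
  if (ltp_s <= 0)
    stop(sprintf(paste0("infeasible resorption targets: nre_target = %g%% with ",
                        "resorbed_np_target = %g implies senesced P = %g g/kg ",
                        "(<= 0) at LTN = %g, LTP = %g, mlcf = %g"),
                 nre_target, resorbed_np_target, ltp_s, LTN, LTP, mlcf),
         call. = FALSE)
  c(LTN_s = ltn_s, LTP_s = ltp_s)
}

# Draw a feasible (nre, resorbed-ratio) pair by bounded rejection; error if
# the configured parameter combination never yields positive senesced P.
.draw_resorption_targets <- function(cfg, LTN, LTP, leaf_np, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    nre_t <- stats::rnorm(1, cfg$nre_mean, cfg$nre_sd)
    if (nre_t <= 1 || nre_t >= 99) next
    res_t <- cfg$omega_true * leaf_np^cfg$lambda_true *
      exp(stats::rnorm(1, 0, cfg$resorption_sigma))
    ltp_s <- (LTP - LTN * (nre_t / 100) / res_t) / cfg$mlcf
    if (ltp_s > 0 && LTN * (1 - nre_t / 100) / cfg$mlcf > 0)
      return(list(nre = nre_t, resorbed = res_t))
  }
  stop(sprintf(paste0("generation error: no feasible senesced concentrations for ",
                      "nre_mean = %g, omega_true = %g, lambda_true = %g at ",
                      "LTN = %.3g, LTP = %.3g (senesced P forced <= 0); ",
                      "lower nre_mean or raise omega_true"),
               cfg$nre_mean, cfg$omega_true, cfg$lambda_true, LTN, LTP),
       call. = FALSE)
}

# Multiplicative jitter rescaled so the weighted mean equals `target` exactly.
.jitter_to_mean <- function(target, n, sigma, weights) {
  v <- target * exp(stats::rnorm(n, 0, sigma))
  v * target / cwm(v, weights)
}

#' Generate a synthetic survey/litter/soil dataset with known ground truth
#'
#' Simulates a complete elevational-gradient community survey whose latent
#' parameters are known, so every downstream estimator can be checked by
#' parameter recovery. Per plot: species biomass shares are drawn from a
#' symmetric Dirichlet(1); species green-leaf C and N are lognormal about
#' site means with the configured per-km trends; soil TN:TP is lognormal and
#' the plot's community leaf N:P is set to
#' `np_constant * (soil N:P)^(1/H_true)` times lognormal noise (species leaf
#' P is scaled so the biomass-weighted community value hits that target
#' exactly); senesced N and P are back-solved via [backsolve_senesced()] so
#' that the plot's NRE matches a Normal(`nre_mean`, `nre_sd`) draw and its
#' resorbed N:P matches `omega_true * (leaf N:P)^lambda_true` times lognormal
#' noise. Litter is written species-level for `shrub_sites` and pooled
#' (token [pooled_token()]) elsewhere. Identical seeds give byte-identical
#' tables; each table uses its own sub-stream of the master seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"stoich_sim"`: list with data frames `survey`,
#'   `litter`, `soil` and a `truth` list (`config` plus per-plot latents:
#'   soil N:P, target leaf N:P, realised LTN/LTP, NRE and resorbed-ratio
#'   targets, senesced concentrations).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n_plots <- cfg$n_sites * cfg$plots_per_site
  site <- rep(seq_len(cfg$n_sites), each = cfg$plots_per_site)
  elev <- cfg$elevations[site]
  elev_km <- (elev - min(cfg$elevations)) / 1000
  plot_id <- sprintf("S%dP%d", site, rep(seq_len(cfg$plots_per_site), cfg$n_sites))

  ## soil table (own stream)
  set.seed(.stage_seed(cfg$seed, 1L))
  soil_np <- cfg$soil_np_mean * exp(stats::rnorm(n_plots, 0, cfg$soil_np_sigma))
  tn <- (cfg$soil_tn_base + cfg$soil_tn_slope * elev_km) *
    exp(stats::rnorm(n_plots, 0, cfg$soil_sigma))
  tp <- tn / soil_np
  soil <- data.frame(plot_id = plot_id, elevation = elev, TN = tn, TP = tp,
                     pH = round(8.4 - 0.3 * elev_km +
                                  stats::rnorm(n_plots, 0, 0.1), 2),
                     SWC = round(pmax(1, 5 + 6 * elev_km +
                                        stats::rnorm(n_plots, 0, 1.5)), 2),
                     stringsAsFactors = FALSE)

  ## survey table (own stream)
  set.seed(.stage_seed(cfg$seed, 2L))
  target_np <- cfg$np_constant * soil_np^(1 / cfg$H_true) *
    exp(stats::rnorm(n_plots, 0, cfg$np_sigma))
  survey_rows <- vector("list", n_plots)
  ltn <- ltp <- ltc <- numeric(n_plots)
  for (i in seq_len(n_plots)) {
    s <- sample(cfg$species_range[1L]:cfg$species_range[2L], 1L)
    shares <- stats::rgamma(s, shape = 1)   # symmetric Dirichlet(1)
    shares <- shares / sum(shares)
    total_bm <- (cfg$biomass_base + cfg$biomass_slope * elev_km[i]) *
      exp(stats::rnorm(1, 0, 0.2))
    biomass <- shares * total_bm
    n_mean <- cfg$green_means[["N"]] + cfg$elevation_slopes[["N"]] * elev_km[i]
    c_mean <- cfg$green_means[["C"]] + cfg$elevation_slopes[["C"]] * elev_km[i]
    leaf_n <- n_mean * exp(stats::rnorm(s, 0, cfg$trait_sigma))
    leaf_c <- c_mean * exp(stats::rnorm(s, 0, cfg$trait_sigma / 4))
    ltn[i] <- cwm(leaf_n, biomass)
    ltc[i] <- cwm(leaf_c, biomass)
    ltp[i] <- ltn[i] / target_np[i]
    leaf_p <- .jitter_to_mean(ltp[i], s, cfg$trait_sigma, biomass)
    density <- pmax(1L, round(shares * (50 + 150 * stats::runif(1))))
    survey_rows[[i]] <- data.frame(
      plot_id = plot_id[i], elevation = elev[i],
      species = sprintf("sp_%s_%02d", plot_id[i], seq_len(s)),
      biomass = biomass, density = density,
      leaf_C = leaf_c, leaf_N = leaf_n, leaf_P = leaf_p,
      stringsAsFactors = FALSE)
  }
  survey <- do.call(rbind, survey_rows)
  rownames(survey) <- NULL

  ## litter table (own stream)
  set.seed(.stage_seed(cfg$seed, 3L))
  litter_rows <- vector("list", n_plots)
  nre_t <- res_t <- ltn_s <- ltp_s <- numeric(n_plots)
  for (i in seq_len(n_plots)) {
    leaf_np <- ltn[i] / ltp[i]
    tgt <- .draw_resorption_targets(cfg, ltn[i], ltp[i], leaf_np)
    nre_t[i] <- tgt$nre; res_t[i] <- tgt$resorbed
    sen <- backsolve_senesced(ltn[i], ltp[i], tgt$nre, tgt$resorbed, cfg$mlcf)
    ltn_s[i] <- sen[["LTN_s"]]; ltp_s[i] <- sen[["LTP_s"]]
    if (site[i] %in% cfg$shrub_sites) {
      sp <- survey_rows[[i]]
      litter_rows[[i]] <- data.frame(
        plot_id = plot_id[i], species = sp$species,
        senesced_N = .jitter_to_mean(ltn_s[i], nrow(sp), cfg$litter_sigma, sp$biomass),
        senesced_P = .jitter_to_mean(ltp_s[i], nrow(sp), cfg$litter_sigma, sp$biomass),
        stringsAsFactors = FALSE)
    } else {
      litter_rows[[i]] <- data.frame(
        plot_id = plot_id[i], species = POOLED_TOKEN,
        senesced_N = ltn_s[i], senesced_P = ltp_s[i],
        stringsAsFactors = FALSE)
    }
  }
  litter <- do.call(rbind, litter_rows)
  rownames(litter) <- NULL

  truth <- list(
    config = unclass(cfg),
    plots = data.frame(
      plot_id = plot_id, site = site, elevation = elev,
      soil_NP = soil_np, target_leaf_NP = target_np,
      LTC = ltc, LTN = ltn, LTP = ltp,
      nre_target = nre_t, resorbed_np_target = res_t,
      LTN_s = ltn_s, LTP_s = ltp_s,
      stringsAsFactors = FALSE)
  )
  structure(list(survey = survey, litter = litter, soil = soil, truth = truth),
            class = "stoich_sim")
}

#' @export
print.stoich_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("synthetic stoichiometry dataset: %d plots (%d sites x %d), %d survey rows\n",
              nrow(x$soil), cfg$n_sites, cfg$plots_per_site, nrow(x$survey)))
  cat(sprintf("  truth: lambda = %g, omega = %g, H = %g, NRE ~ N(%g, %g)\n",
              cfg$lambda_true, cfg$omega_true, cfg$H_true, cfg$nre_mean,
              cfg$nre_sd))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `survey.csv`, `litter.csv`, `soil.csv` and `truth.json` (all latent
#' parameters and per-plot latents) into a directory.
#'
#' @param sim A `"stoich_sim"` object from [generate_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "stoich_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(sim$survey, file.path(dir, "survey.csv"))
  write_table(sim$litter, file.path(dir, "litter.csv"))
  write_table(sim$soil, file.path(dir, "soil.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
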