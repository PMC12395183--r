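test_that("identical seeds give identical datasets", {
  a <- generate_dataset(simulation_config(seed = 5))
  b <- generate_dataset(simulation_config(seed = 5))
  expect_identical(a$survey, b$survey)
  expect_identical(a$litter, b$litter)
  expect_identical(a$soil, b$soil)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(simulation_config(seed = 6))
  expect_false(identical(a$survey, c$survey))
})

test_that("backsolve_senesced inverts the resorption equations exactly", {
  sen <- backsolve_senesced(20, 2, 61.9, 10, mlcf = 0.762)
  expect_equal(unname(sen["LTN_s"]), 10, tolerance = 1e-12)
  set.seed(71)
  for (i in 1:30) {
    ltn <- stats::runif(1, 10, 35)
    ltp <- stats::runif(1, 0.8, 3)
    nre <- stats::runif(1, 40, 90)
    # keep the implied senesced P positive
    rnp <- stats::runif(1, 1.2, 3) * ltn * (nre / 100) / ltp
    mlcf <- stats::runif(1, 0.5, 1)
    sen <- backsolve_senesced(ltn, ltp, nre, rnp, mlcf)
    expect_true(all(sen > 0))
    expect_equal(nure(ltn, sen[["LTN_s"]], mlcf), nre, tolerance = 1e-10)
    expect_equal(resorbed_np(ltn, ltp, sen[["LTN_s"]], sen[["LTP_s"]], mlcf),
                 rnp, tolerance = 1e-10)
  }
})

test_that("infeasible resorption targets raise a named feasibility error", {
  # resorbed N is 16 g/kg; a target ratio of 5 would need 3.2 g/kg of
  # resorbed P from only 2 g/kg of green-leaf P
  expect_error(backsolve_senesced(20, 2, 80, 5), "infeasible")
  expect_error(backsolve_senesced(20, 2, 120, 10), "nre_target")
  expect_error(backsolve_senesced(20, 2, 80, -1), "positive")
})

test_that("a config that forces negative senesced P errors with the parameters named", {
  cfg <- simulation_config(seed = 1, lambda_true = 0.5, omega_true = 1)
  expect_error(generate_dataset(cfg), "omega_true")
})

test_that("generated datasets are internally consistent and validate cleanly", {
  for (seed in c(2, 17)) {
    sim <- generate_dataset(simulation_config(seed = seed))
    expect_identical(nrow(validate_dataset(sim$survey, sim$litter, sim$soil)), 0L)
    expect_true(all(sim$survey[c("leaf_C", "leaf_N", "leaf_P")] > 0))
    expect_true(all(sim$litter[c("senesced_N", "senesced_P")] > 0))
    expect_true(all(sim$soil$TN > 0 & sim$soil$TP > 0))
  }
})

test_that("the pipeline reproduces the generator's latent plot values", {
  sim <- generate_dataset(simulation_config(seed = 8))
  tr <- traits_from_sim(sim)
  m <- match(sim$truth$plots$plot_id, tr$plot_id)
  expect_equal(tr$LTN[m], sim$truth$plots$LTN, tolerance = 1e-10)
  expect_equal(tr$ratio_NP[m], sim$truth$plots$target_leaf_NP, tolerance = 1e-10)
  rs <- resorption_table(tr, sim$litter, survey = sim$survey)
  m <- match(sim$truth$plots$plot_id, rs$plot_id)
  expect_equal(rs$NRE[m], sim$truth$plots$nre_target, tolerance = 1e-8)
  expect_equal(rs$resorbed_NP[m], sim$truth$plots$resorbed_np_target,
               tolerance = 1e-8)
})

test_that("NRE draws track the configured mean", {
  cfg <- simulation_config(seed = 12, n_sites = 10, plots_per_site = 5)
  sim <- generate_dataset(cfg)
  n <- nrow(sim$truth$plots)
  expect_lt(abs(mean(sim$truth$plots$nre_target) - cfg$nre_mean),
            2 * cfg$nre_sd / sqrt(n))
})

test_that("litter is species-level at shrub sites and pooled elsewhere", {
  sim <- generate_dataset(simulation_config(seed = 4))
  shrub_plots <- sim$truth$plots$plot_id[sim$truth$plots$site %in% 1:2]
  herb_plots <- setdiff(sim$truth$plots$plot_id, shrub_plots)
  sp <- sim$litter$species[sim$litter$plot_id %in% shrub_plots]
  expect_true(all(sp != pooled_token()))
  sp <- sim$litter$species[sim$litter$plot_id %in% herb_plots]
  expect_true(all(sp == pooled_token()))
})

test_that("a stoichiometric-control regime is recovered end to end", {
  sim <- generate_dataset(simulation_config(seed = 13, lambda_true = 1,
                                            omega_true = 1,
                                            resorption_sigma = 0.02))
  cs <- strategy_from_sim(sim)
  expect_identical(cs$label, "stoichiometric control")
  expect_lt(abs(cs$lambda - 1), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(nre_mean = 120), "nre_mean")
  expect_error(simulation_config(elevations = c(3000, 2000, 2500, 2600, 2700, 2800)),
               "increasing")
  expect_error(simulation_config(trait_sigma = -1), "sigma")
  expect_error(simulation_config(n_sites = 3, elevations = c(2000, 2500)),
               "length")
})

test_that("write_dataset produces readable tables plus a truth record", {
  sim <- generate_dataset(simulation_config(seed = 15))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("survey.csv", "litter.csv",
                                               "soil.csv", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$config$lambda_true, 0.912)
  back <- read_survey_table(file.path(dir, "survey.csv"))
  expect_equal(back$leaf_N, sim$survey$leaf_N, tolerance = 1e-12)
})
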