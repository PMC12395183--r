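test_that("nure matches the mass-loss-corrected formula", {
  expect_equal(nure(20, 10, 0.762), 61.9, tolerance = 1e-12)
  expect_equal(nure(15, 15, 0.762), 23.8, tolerance = 1e-12)  # ratio 1 forces (1 - mlcf)*100
  expect_equal(nure(20, 0, 0.5), 100)
  expect_error(nure(0, 5), "positive")
  expect_error(nure(20, -1), "non-negative")
  expect_error(nure(20, 5, 1.5), "mlcf")
})

test_that("nure is strictly decreasing in senesced and in mlcf, identity at mlcf = 1", {
  set.seed(31)
  for (i in 1:20) {
    g <- stats::runif(1, 5, 40)
    s <- sort(stats::runif(2, 0.1, g))
    expect_gt(nure(g, s[1]), nure(g, s[2]))
    m <- sort(stats::runif(2, 0.3, 1))
    expect_gt(nure(g, s[1], m[1]), nure(g, s[1], m[2]))
    expect_equal(nure(g, s[1], 1), (1 - s[1] / g) * 100, tolerance = 1e-12)
  }
})

test_that("resorbed_np matches hand arithmetic and flags accretion as undefined", {
  expect_equal(resorbed_np(20, 2, 10, 1, mlcf = 1), 10, tolerance = 1e-12)
  expect_equal(resorbed_np(20, 2, 10, 1, mlcf = 0.762),
               (20 - 10 * 0.762) / (2 - 1 * 0.762), tolerance = 1e-12)
  expect_true(is.na(resorbed_np(20, 2, 10, 3, mlcf = 0.762)))  # P accretion
  expect_error(resorbed_np(20, 2, -1, 1), "positive")
})

test_that("resorbed_np is invariant to rescaling all concentrations", {
  set.seed(32)
  for (i in 1:20) {
    v <- stats::runif(4, 0.5, 30)
    v[1] <- v[3] + stats::runif(1, 1, 10)   # ensure resorption of both nutrients
    v[2] <- v[4] + stats::runif(1, 1, 10)
    k <- stats::runif(1, 0.01, 50)
    expect_equal(resorbed_np(v[1], v[2], v[3], v[4], 0.9),
                 resorbed_np(k * v[1], k * v[2], k * v[3], k * v[4], 0.9),
                 tolerance = 1e-10)
  }
})

test_that("community_resorption handles pooled and species-level litter", {
  green <- data.frame(plot_id = "P1", LTN = 20, LTP = 2)
  pooled <- data.frame(plot_id = "P1", species = pooled_token(),
                       senesced_N = 5, senesced_P = 0.5)
  out <- community_resorption(green, pooled)
  expect_equal(out$NRE, nure(20, 5), tolerance = 1e-12)   # 80.95

  # two litter species with equal biomass: senesced P pools to 0.5
  litter <- data.frame(plot_id = "P1", species = c("a", "b"),
                       senesced_N = c(5, 5), senesced_P = c(0.4, 0.6))
  survey_plot <- data.frame(plot_id = "P1", species = c("a", "b"),
                            biomass = c(3, 3))
  out <- community_resorption(green, litter, survey_plot = survey_plot)
  expect_equal(out$PRE, (1 - 0.762 * 0.25) * 100, tolerance = 1e-12)  # 80.95

  # litter identical to green leaves: NRE = PRE = (1 - mlcf)*100, ratio 1
  same <- data.frame(plot_id = "P1", species = pooled_token(),
                     senesced_N = 20, senesced_P = 2)
  out <- community_resorption(green, same)
  expect_equal(out$NRE, 23.8, tolerance = 1e-12)
  expect_equal(out$PRE, 23.8, tolerance = 1e-12)
  expect_equal(out$ratio_NRE_PRE, 1, tolerance = 1e-12)
})

test_that("species-level litter missing from the survey falls back with a warning", {
  green <- data.frame(plot_id = "P1", LTN = 20, LTP = 2)
  litter <- data.frame(plot_id = "P1", species = c("ghost1", "ghost2"),
                       senesced_N = c(4, 6), senesced_P = c(0.4, 0.6))
  survey_plot <- data.frame(plot_id = "P1", species = "other", biomass = 5)
  expect_warning(out <- community_resorption(green, litter,
                                             survey_plot = survey_plot),
                 "unweighted")
  expect_equal(out$NRE, nure(20, 5), tolerance = 1e-12)
})

test_that("undefined resorbed ratios are flagged and excluded from fits", {
  green <- data.frame(plot_id = "P1", LTN = 20, LTP = 2)
  accrete <- data.frame(plot_id = "P1", species = pooled_token(),
                        senesced_N = 5, senesced_P = 3)
  out <- community_resorption(green, accrete)
  expect_true(is.na(out$resorbed_NP))
  expect_match(out$flags, "excluded-from-fit")
})

test_that("control_strategy recovers exact proportionality as stoichiometric control", {
  x <- seq(8, 22, length.out = 10)
  cs <- control_strategy(x, x)
  expect_equal(cs$lambda, 1, tolerance = 1e-10)
  expect_equal(cs$omega, 1, tolerance = 1e-10)
  expect_equal(cs$linear_slope, 1, tolerance = 1e-10)
  expect_identical(cs$label, "stoichiometric control")
  expect_identical(cs$n_used, 10L)
})

test_that("control_strategy recovers noise-free power laws to 6 significant digits", {
  x <- exp(seq(log(8), log(25), length.out = 12))
  for (lam in c(0.5, 0.912, 1)) {
    cs <- control_strategy(x, 1.33 * x^lam)
    expect_equal(cs$lambda, lam, tolerance = 1e-7)
    expect_equal(cs$omega, 1.33, tolerance = 1e-6)
  }
})

test_that("a shallow power law with noise is labelled nutrient limitation control", {
  set.seed(41)
  x <- stats::rlnorm(60, log(14), 0.2)
  y <- 1 * x^0.5 * exp(stats::rnorm(60, 0, 0.05))
  cs <- control_strategy(x, y)
  expect_gte(cs$lambda, 0.45)
  expect_lte(cs$lambda, 0.55)
  expect_lt(cs$lambda_ci[2], 1)
  expect_identical(cs$label, "nutrient limitation control")
})

test_that("control_strategy enforces the minimum sample size and counts exclusions", {
  expect_error(control_strategy(c(10, 12), c(9, 11)), "insufficient")
  cs <- control_strategy(c(10, 12, 14, 16, NA), c(9, 11, 13, 15, 2))
  expect_identical(cs$n_used, 4L)
  expect_identical(cs$n_excluded, 1L)
})

test_that("confidence intervals bracket the point estimates", {
  set.seed(42)
  x <- stats::rlnorm(24, log(13), 0.1)
  y <- 1.2 * x^0.9 * exp(stats::rnorm(24, 0, 0.08))
  cs <- control_strategy(x, y)
  expect_lte(cs$lambda_ci[1], cs$lambda)
  expect_gte(cs$lambda_ci[2], cs$lambda)
  expect_lte(cs$linear_slope_ci[1], cs$linear_slope)
  expect_gte(cs$linear_slope_ci[2], cs$linear_slope)
  ci <- confint(cs)
  expect_equal(unname(ci["lambda", ]), cs$lambda_ci, tolerance = 1e-10)
})
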