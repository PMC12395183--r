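test_that("fit_homeostasis recovers noiseless power laws to 6 significant digits", {
  x <- exp(seq(log(0.3), log(4), length.out = 12))
  for (H0 in c(1, 2, 4, 16, 16.34)) {
    f <- fit_homeostasis(x, 2 * x^(1 / H0))
    expect_equal(f$H, H0, tolerance = 1e-7)
    expect_equal(f$c, 2, tolerance = 1e-7)
  }
})

test_that("the identity relation gives H = 1 and a sensitive state", {
  x <- seq(0.5, 5, length.out = 10)
  f <- fit_homeostasis(x, x)
  expect_equal(f$H, 1, tolerance = 1e-10)
  expect_lt(f$p_value, 0.05)
  expect_identical(f$label, "sensitive state")
})

test_that("y = 2 x^0.25 is a steady state at the H = 4 band edge", {
  x <- exp(seq(log(0.2), log(6), length.out = 10))
  f <- fit_homeostasis(x, 2 * x^0.25)
  expect_equal(f$H, 4, tolerance = 1e-8)
  expect_identical(f$label, "steady state")
})

test_that("plant values decoupled from soil give an absolute steady state", {
  set.seed(53)
  x <- stats::rlnorm(24, 0, 0.5)
  y <- stats::rlnorm(24, log(14), 0.1)   # independent of x
  f <- fit_homeostasis(x, y)
  expect_gt(f$p_value, 0.05)
  expect_identical(f$H, Inf)
  expect_identical(f$label, "absolute steady state")
})

test_that("H is equivariant to rescaling the soil axis and to the log base", {
  set.seed(54)
  x <- stats::rlnorm(30, 0, 0.4)
  y <- 3 * x^(1 / 5) * exp(stats::rnorm(30, 0, 0.02))
  f1 <- fit_homeostasis(x, y)
  f2 <- fit_homeostasis(7 * x, y)
  expect_equal(f1$H, f2$H, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$c, f2$c)))
  # change of base: natural-log OLS slope must equal 1/H too
  nat <- stats::lm(log(y) ~ log(x))
  expect_equal(f1$H, 1 / unname(coef(nat)[2]), tolerance = 1e-9)
})

test_that("fit_homeostasis rejects degenerate input", {
  expect_error(fit_homeostasis(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_homeostasis(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(fit_homeostasis(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("homeostasis recovery within 15% under moderate noise", {
  set.seed(55)
  x <- stats::rlnorm(50, 0, 0.8)
  y <- 13 * x^(1 / 4) * exp(stats::rnorm(50, 0, 0.05))
  f <- fit_homeostasis(x, y)
  expect_lt(abs(f$H - 4) / 4, 0.15)
})

test_that("Persson bands classify H with inclusive left endpoints", {
  expect_identical(classify_homeostasis(16.34, 0.01), "steady state")
  expect_identical(classify_homeostasis(4, 0.01), "steady state")
  expect_identical(classify_homeostasis(3.99, 0.01), "weak steady state")
  expect_identical(classify_homeostasis(2, 0.01), "weak steady state")
  expect_identical(classify_homeostasis(1.33, 0.01), "weak sensitive state")
  expect_identical(classify_homeostasis(1.32, 0.01), "sensitive state")
  expect_identical(classify_homeostasis(3, 0.2), "absolute steady state")
  expect_identical(classify_homeostasis(Inf, 0.2), "absolute steady state")
})

test_that("limitation thresholds follow both published schemes", {
  expect_identical(classify_limitation(16.39, "guesewell_10_20"), "co-limited")
  expect_identical(classify_limitation(9, "guesewell_10_20"), "N-limited")
  expect_identical(classify_limitation(21, "guesewell_10_20"), "P-limited")
  expect_identical(classify_limitation(16.39, "koerselman_14_16"), "P-limited")
  expect_identical(classify_limitation(13.9, "koerselman_14_16"), "N-limited")
  expect_identical(classify_limitation(15, "koerselman_14_16"), "co-limited")
  expect_error(classify_limitation(15, "other"), "arg")
  expect_error(classify_limitation(-2), "positive")
})

test_that("limitation boundaries are closed intervals", {
  expect_identical(classify_limitation(10, "guesewell_10_20"), "co-limited")
  expect_identical(classify_limitation(20, "guesewell_10_20"), "co-limited")
  expect_identical(classify_limitation(14, "koerselman_14_16"), "co-limited")
  expect_identical(classify_limitation(16, "koerselman_14_16"), "co-limited")
})

test_that("labels are monotone non-decreasing toward P-limited in the ratio", {
  lv <- c("N-limited" = 1, "co-limited" = 2, "P-limited" = 3)
  for (scheme in c("guesewell_10_20", "koerselman_14_16")) {
    lab <- classify_limitation(seq(1, 30, by = 0.25), scheme)
    expect_true(all(diff(lv[lab]) >= 0))
  }
})

test_that("homeostasis_table pairs plots and fits all three traits", {
  sim <- generate_dataset(simulation_config(seed = 9))
  tr <- traits_from_sim(sim)
  hm <- homeostasis_table(tr, sim$soil)
  expect_identical(hm$trait, c("N", "P", "N:P"))
  expect_identical(hm$n, rep(24L, 3))
  expect_true(all(hm$H > 0))
  finite <- is.finite(hm$H)
  expect_equal(hm$H[finite] * hm$slope[finite], rep(1, sum(finite)),
               tolerance = 1e-10)
})
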