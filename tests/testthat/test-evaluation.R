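# evaluation metrics and the synthetic observed-data generator

test_that("mean prediction error follows the relative-error average", {
  expect_equal(mpe(c(1, 2), c(1, 2)), 0)
  expect_equal(mpe(c(1, 2), c(2, 2)), 50)
  expect_equal(mpe(c(1, 2, 4), 2 * c(1, 2, 4)), 100)
  # invariant under uniform rescaling of both vectors
  o <- c(0.5, 1.2, 3)
  s <- c(0.7, 1.0, 2.5)
  expect_equal(mpe(10 * o, 10 * s), mpe(o, s))
  expect_error(mpe(c(1, 0), c(1, 1)), "> 0")
  expect_error(mpe(1:3, 1:2), "equal length")
})

test_that("mean squared error is symmetric and scales quadratically", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 2), c(2, 2)), 0.5)
  o <- c(0.5, 1.2, 3)
  s <- c(0.7, 1.0, 2.5)
  expect_equal(mse(o, s), mse(s, o))
  expect_equal(mse(3 * o, 3 * s), 9 * mse(o, s))
})

test_that("trapezoidal AUC is exact for piecewise-linear profiles", {
  expect_equal(auc_tlast(c(0, 4), c(2, 2)), 8)
  expect_equal(auc_tlast(c(0, 1, 2), c(0, 2, 0)), 2)
  t <- seq(0, 10, by = 0.01)
  expect_equal(auc_tlast(t, exp(-t)), 1 - exp(-10), tolerance = 1e-4)
  # lower bound restricts the window
  expect_equal(auc_tlast(c(0, 1, 2, 3), c(1, 1, 1, 1), from_time_h = 2), 1)
  expect_error(auc_tlast(c(0), c(1)), "two points")
  expect_error(auc_tlast(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("percent difference reproduces the exposure-table arithmetic", {
  expect_equal(round(percent_difference(0.67, 0.85), 1), 26.9)
  expect_equal(round(percent_difference(15.0, 16.5), 1), 10.0)
  expect_equal(percent_difference(3, 3), 0)
  expect_error(percent_difference(0, 1), "> 0")
})

test_that("dose normalisation assumes linear pharmacokinetics", {
  ds <- observed_dataset("cefuroxime", "maternal_plasma",
                         dose_mg = c(1500, 750), time_h = c(1, 2),
                         conc_ug_mL = c(40, 10))
  dn <- dose_normalize(ds, 750)
  expect_equal(dn$conc_ug_mL, c(20, 10))
  expect_equal(unique(dn$dose_mg), 750)
  ds5 <- observed_dataset("diazepam", "umbilical_vein", 5, 1, 1.0)
  expect_equal(dose_normalize(ds5, 10)$conc_ug_mL, 2.0)
})

test_that("observed datasets validate and round-trip through CSV", {
  expect_error(observed_dataset("x", "umbilical_vein", 10, -1, 1),
               ">= 0")
  expect_error(observed_dataset("x", "umbilical_vein", 10, 1, 0), "> 0")
  expect_error(observed_dataset("x", "cord", 10, 1, 1), "matrix")
  ds <- observed_dataset("diazepam", "umbilical_vein", 10,
                         c(0.5, 2, 6), c(0.08, 0.12, 0.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed(ds, path)
  expect_equal(read_observed(path), ds)
})

test_that("the fixture generator reproduces the truth at zero noise and is seeded", {
  t <- seq(0, 24, by = 0.1)
  c_true <- 5 * exp(-0.2 * t)
  fx0 <- generate_observed_fixture(t, c_true, n_samples = 15,
                                   error_cv = 0, seed = 9)
  expect_equal(fx0$conc_ug_mL,
               interpolate_profile(t, c_true, fx0$time_h))
  fx1 <- generate_observed_fixture(t, c_true, n_samples = 15,
                                   error_cv = 0.3, seed = 9)
  fx2 <- generate_observed_fixture(t, c_true, n_samples = 15,
                                   error_cv = 0.3, seed = 9)
  expect_identical(fx1, fx2)
  expect_false(identical(
    fx1, generate_observed_fixture(t, c_true, n_samples = 15,
                                   error_cv = 0.3, seed = 10)))
})

test_that("fixture noise carries the documented lognormal median-vs-mean offset", {
  t <- seq(0, 24, by = 0.1)
  c_true <- 5 * exp(-0.2 * t)
  cv <- 0.3
  n <- 10000
  fx <- generate_observed_fixture(t, c_true, n_samples = n,
                                  error_cv = cv, seed = 123)
  sim_at <- interpolate_profile(t, c_true, fx$time_h)
  got <- mpe(fx$conc_ug_mL, sim_at)
  # E[1/LN(0, s)] = exp(s^2/2) with s^2 = log(1 + CV^2)
  expected <- 100 * (exp(log(1 + cv^2) / 2) - 1)
  expect_lt(abs(got - expected), 100 * 3 * cv / sqrt(n))
})

test_that("prediction evaluation interpolates simulation onto observations", {
  t <- seq(0, 12, by = 0.5)
  prof <- 3 * exp(-0.3 * t)
  obs <- generate_observed_fixture(t, prof, n_samples = 8, error_cv = 0,
                                   seed = 2)
  ev <- evaluate_predictions(obs, t, prof)
  expect_equal(ev$mpe_pct, 0, tolerance = 1e-9)
  expect_equal(ev$mse, 0, tolerance = 1e-12)
  expect_equal(ev$n, 8)
  expect_gt(ev$auc_pred, 0)
})
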