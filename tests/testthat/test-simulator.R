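# assembled system: identities, oracle, population machinery

test_that("zero dose yields identically zero profiles", {
  sim <- simulate(pbpk_model("diazepam"), tmax_h = 4, dt_min = 10,
                  dose_scale = 0)
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$amounts == 0))
})

test_that("forcing equal fractions unbound reproduces the single-fu implementation", {
  for (nm in c("diazepam", "cefuroxime")) {
    d <- get_drug(nm)
    d$fu_fetal <- d$fu_maternal
    sA <- simulate(pbpk_model(d), tmax_h = 12, dt_min = 10,
                   rtol = 1e-12, atol = 1e-12)
    sB <- simulate(pbpk_model(d, exchange = "legacy"), tmax_h = 12,
                   dt_min = 10, rtol = 1e-12, atol = 1e-12)
    expect_equal(sA$conc, sB$conc, tolerance = 1e-9)
  }
})

test_that("the integrator matches the matrix-exponential solution of the linear system", {
  mod <- pbpk_model("cefuroxime")
  parms <- mfpbpk:::model_parms(mod)
  A <- matrix(0, 23, 23)
  for (j in 1:23) {
    e <- numeric(23)
    e[j] <- 1
    A[, j] <- mfpbpk:::model_rhs(0, e, parms)[[1]]
  }
  y0 <- numeric(23)
  y0[1] <- 750 / 424.39 * 1000
  sim <- simulate(mod, tmax_h = 6, dt_min = 60, rtol = 1e-12,
                  atol = 1e-12)
  for (tt in c(60, 180, 360)) {
    ref <- as.numeric(Matrix::expm(A * tt) %*% y0)
    got <- sim$amounts[sim$time_min == tt, ]
    big <- abs(ref) > 1e-10 * max(abs(ref))
    expect_lt(max(abs(got[big] - ref[big]) / abs(ref[big])), 1e-6)
  }
})

test_that("halving solver tolerances leaves the reported AUC unchanged", {
  mod <- pbpk_model("ondansetron")
  a1 <- simulate(mod, tmax_h = 12, dt_min = 5, rtol = 1e-8, atol = 1e-8)
  a2 <- simulate(mod, tmax_h = 12, dt_min = 5, rtol = 5e-9, atol = 5e-9)
  auc1 <- auc_tlast(a1$time_min / 60, a1$conc[, "umbilical_vein"])
  auc2 <- auc_tlast(a2$time_min / 60, a2$conc[, "umbilical_vein"])
  expect_lt(abs(auc1 - auc2) / auc1, 1e-4)  # < 0.01%
})

test_that("population summaries behave at the degenerate corners", {
  mod <- pbpk_model("ondansetron")
  # n = 1: geomean and both percentiles are the single profile
  pop <- simulate_population(mod, population_spec(n = 1, seed = 5),
                             tmax_h = 6, dt_min = 10)
  expect_equal(pop$summary$umbilical_vein$geomean,
               as.numeric(pop$umbilical_vein[1, ]))
  expect_equal(pop$summary$umbilical_vein$p5,
               pop$summary$umbilical_vein$p95)
  # all CVs zero: identical individuals
  spec0 <- population_spec(n = 3, cv_map = c(CL_hepatic = 0), seed = 5)
  pop0 <- simulate_population(mod, spec0, tmax_h = 6, dt_min = 10)
  expect_equal(pop0$umbilical_vein[1, ], pop0$umbilical_vein[3, ])
})

test_that("population runs are seed-reproducible and extensible in n", {
  mod <- pbpk_model("ondansetron")
  p1 <- simulate_population(mod, population_spec(n = 4, seed = 42),
                            tmax_h = 6, dt_min = 10)
  p2 <- simulate_population(mod, population_spec(n = 4, seed = 42),
                            tmax_h = 6, dt_min = 10)
  expect_identical(p1$summary, p2$summary)
  # growing n keeps earlier individuals in place
  p3 <- simulate_population(mod, population_spec(n = 6, seed = 42),
                            tmax_h = 6, dt_min = 10)
  expect_identical(p3$umbilical_vein[1:4, ], p1$umbilical_vein)
  # variability actually spreads the band
  expect_true(any(p3$summary$umbilical_vein$p95 >
                    p3$summary$umbilical_vein$p5))
})

test_that("repeated regimens are integrated to periodic steady state", {
  sim <- simulate(pbpk_model("raltegravir"), dt_min = 10)
  expect_false(is.na(sim$ss_doses))
  expect_gte(sim$ss_doses, 2L)
  # reported window is one dosing interval, re-based to the dose
  expect_equal(sim$time_min[1], 0)
  expect_lte(max(sim$time_min), 12 * 60)
})

test_that("model object methods report the assembled parameters", {
  mod <- pbpk_model("metronidazole")
  expect_output(print(mod), "flow_limited")
  co <- coef(mod)
  expect_equal(unname(co["CL_apical"]), 9.76)
  expect_equal(unname(co["f_in"]), 1)
  s <- summary(mod)
  expect_equal(s$quasi_equilibrium_fetal_maternal, 0.92 / 0.89)
  expect_output(print(s), "quasi-equilibrium")
  sim <- simulate(mod, tmax_h = 2, dt_min = 30)
  df <- as.data.frame(sim)
  expect_true(all(c("time_min", "compartment",
                    "concentration_ug_per_mL") %in% names(df)))
})

test_that("equal-fu comparison is exactly null when binding is already equal", {
  d <- get_drug("ondansetron")
  d$fu_fetal <- d$fu_maternal
  cmp <- compare_fu(d, tmax_h = 6, dt_min = 10)
  expect_identical(cmp$difference_pct, 0)
})

test_that("lower fetal binding raises fetal exposure across a symmetric barrier", {
  # fu_fetal < fu_maternal means more unbound drug on the fetal side at
  # equal total concentration; exposure equilibrates higher
  cmp <- compare_fu("diazepam", tmax_h = 24, dt_min = 5)
  expect_gt(cmp$difference_pct, 0)
})
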