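# exchange-matrix structure and fetal compartment right-hand side

test_that("exchange matrix conserves mass for randomized parameters", {
  set.seed(7)
  for (i in 1:200) {
    E <- build_exchange_matrix(random_geometry(), random_drug(),
                               g_in = runif(1, 0.1, 5),
                               g_out = runif(1, 0.1, 5))
    expect_lt(max(abs(colSums(E$E))), 1e-13 * max(abs(E$E)))
    expect_true(all(diag(E$E) <= 0))
    off <- E$E; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("zero membrane permeabilities decouple to the bc/pls block", {
  g <- fetal_geometry()$fetus
  g$P_end <- 0
  g$P_int_cell <- 0
  d <- test_drug()
  E <- build_exchange_matrix(g, d)$E
  expect_equal(E[3:4, ], matrix(0, 2, 4), ignore_attr = TRUE)
  expect_equal(E[, 3:4], matrix(0, 4, 2), ignore_attr = TRUE)
  cl <- g$P_pls_bc * g$SA_bc / 1000 * d$fu_fetal
  expect_equal(E[1, 1], -cl / d$K_bc)
  expect_equal(E[1, 2], cl)
})

test_that("equal maternal and fetal fu reproduces the single-fu matrix exactly", {
  for (nm in c("diazepam", "metronidazole", "ondansetron")) {
    d <- get_drug(nm)
    d$fu_fetal <- d$fu_maternal
    g <- fetal_geometry()$fetus
    expect_equal(build_exchange_matrix(g, d)$E,
                 legacy_exchange_matrix(g, d)$E, tolerance = 1e-14)
  }
})

test_that("compartment rates vanish at equilibrium and conserve mass without flow", {
  d <- test_drug()
  g <- fetal_geometry()$fetus
  E <- build_exchange_matrix(g, d)
  r <- equilibrium_concentration_ratios(d)
  C_pls <- 2.5
  eq_amounts <- c(C_pls * r["bc_pls"] * g$V_bc, C_pls * g$V_pls,
                  C_pls * r["int_pls"] * g$V_int,
                  C_pls * r["cell_pls"] * g$V_cell)
  rates <- fetal_rhs(eq_amounts, c(C_pls * r["bc_pls"], C_pls), g, E,
                     hct = 0.45)
  expect_equal(rates, rep(0, 4), tolerance = 1e-12)

  # no perfusion: rates reduce to E C and sum to zero for any state
  g0 <- g; g0$Q <- 0
  set.seed(11)
  for (i in 1:20) {
    amounts <- runif(4, 0, 10)
    rates <- fetal_rhs(amounts, c(0, 0), g0, E, hct = 0.45)
    V <- c(g0$V_bc, g0$V_pls, g0$V_int, g0$V_cell)
    expect_equal(rates, as.numeric(E$E %*% (amounts / V)))
    expect_lt(abs(sum(rates)), 1e-12 * max(abs(rates)))
  }
  g0$V_bc <- 0
  expect_error(fetal_rhs(c(1, 1, 1, 1), c(0, 0), g0, E, 0.45),
               "zero-volume")
})

test_that("zero-flux ratios match the long-run plateau of a constant-inflow simulation", {
  d <- get_drug("diazepam")
  mod <- pbpk_model(d, maternal_mode = "constant",
                    const_maternal_conc = 10)
  sim <- simulate(mod, tmax_h = 24 * 7, dt_min = 240, dose_scale = 0)
  last <- nrow(sim$amounts)
  V <- sim$volumes
  C_pls <- unname(sim$amounts[last, "fe_pls"] / V["fe_pls"])
  C_int <- unname(sim$amounts[last, "fe_int"] / V["fe_int"])
  C_cell <- unname(sim$amounts[last, "fe_cell"] / V["fe_cell"])
  r <- equilibrium_concentration_ratios(d)
  expect_equal(C_int / C_pls, unname(r["int_pls"]), tolerance = 1e-3)
  expect_equal(C_cell / C_pls, unname(r["cell_pls"]), tolerance = 1e-3)
})

test_that("ratios scale linearly with the intracellular partition coefficient", {
  d <- test_drug()
  d2 <- d
  d2$K_cell_pls_fetal <- d$K_cell_pls_fetal * 2
  r1 <- equilibrium_concentration_ratios(d)
  r2 <- equilibrium_concentration_ratios(d2)
  expect_equal(r2["cell_pls"], 2 * r1["cell_pls"])
  expect_equal(r2["int_pls"], r1["int_pls"])
})

test_that("the amniotic fluid pool exchanges with nothing", {
  mod <- pbpk_model("metronidazole")
  parms <- mfpbpk:::model_parms(mod)
  set.seed(3)
  for (i in 1:10) {
    y <- runif(23, 0, 100)
    d <- mfpbpk:::model_rhs(0, y, parms)[[1]]
    expect_identical(d[21], 0)
  }
  sim <- simulate(mod, tmax_h = 2, dt_min = 10)
  expect_true(all(sim$amounts[, "amn"] == 0))
})
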