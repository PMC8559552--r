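# trophoblast barrier fluxes, clearances, diagnostics

test_that("apical flux vanishes at partition equilibrium and with zero scaling", {
  expect_equal(apical_flux(10, 0.74 * 10, CL_apical = 1,
                           fu_maternal = 0.88, K_apical = 0.74), 0)
  expect_equal(apical_flux(5, 100, CL_apical = 2, fu_maternal = 0.5,
                           K_apical = 1, f_in = 0, f_out = 0), 0)
  # hand arithmetic for cefuroxime into an empty trophoblast
  expect_equal(apical_flux(10, 0, CL_apical = 0.20, fu_maternal = 0.73,
                           K_apical = 0.61), 1.46)
  expect_error(apical_flux(1, 1, CL_apical = 1, fu_maternal = 0.5,
                           K_apical = 0), "K_apical")
})

test_that("basolateral flux is zero at the equilibrium ratios and factors linearly", {
  d <- test_drug()
  comp <- plasma_composition()
  Kint <- k_int_pls(d$fu_fetal, comp)
  r <- equilibrium_concentration_ratios(d, comp)
  C_pls <- 3
  f0 <- basolateral_flux(C_pls * r["int_pls"], C_pls * r["cell_pls"],
                         P_int_cell = 1e-3, SA_int_cell = 5.67e6,
                         fu_fetal = d$fu_fetal,
                         fu_maternal = d$fu_maternal, K_int_pls = Kint,
                         K_cell_pls = d$K_cell_pls_fetal)
  expect_equal(unname(f0), 0, tolerance = 1e-12)

  # doubling both scaling factors is doubling the permeability
  args <- list(C_int = 2, C_cell = 5, SA_int_cell = 5.67e6,
               fu_fetal = d$fu_fetal, fu_maternal = d$fu_maternal,
               K_int_pls = Kint, K_cell_pls = d$K_cell_pls_fetal)
  a <- do.call(basolateral_flux,
               c(args, P_int_cell = 1e-3, g_in = 2, g_out = 2))
  b <- do.call(basolateral_flux, c(args, P_int_cell = 2e-3))
  expect_equal(a, b)

  # one-sided efflux doubling halves the zero-flux cell:interstitial ratio
  C_int <- 4
  zero_cell <- function(g_out) {
    # solve g_in*P*SA*(fu_f/Kint)*C_int = g_out*P*SA*(fu_m/Kcell)*C_cell
    C_int * (d$fu_fetal / Kint) / (g_out * d$fu_maternal /
                                     d$K_cell_pls_fetal)
  }
  expect_equal(zero_cell(2), zero_cell(1) / 2)
  f <- basolateral_flux(C_int, zero_cell(2), P_int_cell = 1e-3,
                        SA_int_cell = 5.67e6, fu_fetal = d$fu_fetal,
                        fu_maternal = d$fu_maternal, K_int_pls = Kint,
                        K_cell_pls = d$K_cell_pls_fetal, g_out = 2)
  expect_equal(f, 0, tolerance = 1e-12)
})

test_that("basolateral clearance arithmetic converts permeability times area to L/min", {
  expect_equal(signif(basolateral_clearance(2.73e-6, 56700), 2), 0.015)
  expect_equal(signif(basolateral_clearance(1.69e-2, 56700), 2), 96)
  expect_equal(basolateral_clearance(0, 56700), 0)
})

test_that("flow-limitation diagnostic separates metronidazole from the rest", {
  lib <- load_drug_library()
  d <- flow_limitation_diagnostic(lib$metronidazole)
  expect_equal(signif(d$product, 2), 9.0)
  expect_equal(d$regime, "flow_limited")
  d <- flow_limitation_diagnostic(lib$cefuroxime)
  expect_equal(d$product, 0.73 * 0.20)
  expect_equal(d$regime, "permeability_limited")
  d <- flow_limitation_diagnostic(lib$acyclovir)
  expect_equal(d$product, 0.88 * 0.059)
  expect_equal(d$regime, "permeability_limited")
})

test_that("calibrator scaling is a plain linear hook", {
  expect_equal(apical_clearance_from_calibrator(2e-5, 2e-5, 1.5), 1.5)
  expect_equal(apical_clearance_from_calibrator(4e-5, 2e-5, 1.5),
               2 * apical_clearance_from_calibrator(2e-5, 2e-5, 1.5))
  expect_error(apical_clearance_from_calibrator(1e-5, 0, 1),
               "papp_calibrator")
  # scaling one library drug from another by the Caco-2 ratio does not
  # reproduce the library clearance exactly (the calibration behind the
  # library values is richer than a single linear factor)
  lib <- load_drug_library()
  est <- apical_clearance_from_calibrator(
    lib$acyclovir$caco2_papp, lib$diazepam$caco2_papp,
    lib$diazepam$CL_apical)
  expect_false(isTRUE(all.equal(est, lib$acyclovir$CL_apical,
                                tolerance = 1e-3)))
})
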