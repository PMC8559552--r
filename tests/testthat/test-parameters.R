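# drug library contents and config I/O

test_that("drug library carries the full reference table field-for-field", {
  lib <- load_drug_library()
  expect_length(lib, 8L)
  golden <- data.frame(
    name = c("acyclovir", "cefuroxime", "diazepam", "dolutegravir",
             "emtricitabine", "metronidazole", "ondansetron",
             "raltegravir"),
    fu_nonpreg = c(0.85, 0.67, 0.020, 0.0070, 0.96, 0.89, 0.27, 0.17),
    fu_maternal = c(0.88, 0.73, 0.027, 0.0088, 0.97, 0.92, 0.33, 0.24),
    fu_fetal = c(0.86, 0.68, 0.021, 0.0080, 0.96, 0.89, 0.28, 0.23),
    K_cell_pls = c(0.74, 0.61, 0.079, 0.16, 0.83, 0.80, 0.41, 0.28),
    caco2 = c(0.3e-6, 1.2e-6, 8.9e-5, 2.5e-6, NA, 5.7e-5, 1.8e-5,
              7.3e-6),
    CL_apical = c(0.059, 0.20, 15.1, 0.43, 0.019, 9.76, 3.11, 1.24),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(golden))) {
    d <- lib[[golden$name[i]]]
    expect_equal(d$fu_nonpreg, golden$fu_nonpreg[i], info = d$name)
    expect_equal(d$fu_maternal, golden$fu_maternal[i], info = d$name)
    expect_equal(d$fu_fetal, golden$fu_fetal[i], info = d$name)
    expect_equal(d$K_apical, golden$K_cell_pls[i], info = d$name)
    expect_equal(d$K_cell_pls_fetal, golden$K_cell_pls[i], info = d$name)
    expect_equal(d$caco2_papp, golden$caco2[i], info = d$name)
    expect_equal(d$CL_apical, golden$CL_apical[i], info = d$name)
  }
  # regimens: spot-check the three routes
  expect_equal(lib$diazepam$regimen$dose_mg, 10)
  expect_equal(lib$diazepam$regimen$route, "iv_bolus")
  expect_equal(lib$diazepam$regimen$n_doses, 1L)
  expect_equal(lib$cefuroxime$regimen$dose_mg, 750)
  expect_equal(lib$dolutegravir$regimen$dose_mg, 50)
  expect_equal(lib$dolutegravir$regimen$route, "oral")
  expect_equal(lib$dolutegravir$regimen$interval_h, 24)
  expect_equal(lib$raltegravir$regimen$interval_h, 12)
})

test_that("only the cefuroxime and ondansetron basolateral permeabilities are reported values", {
  tab <- read.csv(system.file("extdata", "drug_library.csv",
                              package = "mfpbpk"))
  rep <- tab$name[tab$P_basolateral_source == "reported"]
  expect_setequal(rep, c("cefuroxime", "ondansetron"))
  expect_equal(tab$P_basolateral_cm_min[tab$name == "cefuroxime"], 2.73e-6)
  expect_equal(tab$P_basolateral_cm_min[tab$name == "ondansetron"], 1.69e-2)
})

test_that("container invariants are enforced with errors naming the field", {
  expect_error(dose_regimen(-5, "iv_bolus"), "dose_mg")
  expect_error(dose_regimen(10, "oral", n_doses = 3), "interval_h")
  expect_error(dose_regimen(10, "iv_infusion"), "infusion_duration_min")
  expect_error(test_drug(fu_maternal = 1.3), "fu_maternal")
  expect_error(test_drug(K_cell = -1), "K_apical")
  expect_error(drug_parameters("x", 0.5, 0.5, 0.5, K_apical = 1,
                               K_cell_pls_fetal = -1, CL_apical = 1,
                               P_basolateral = 0, molecular_weight = 100,
                               regimen = dose_regimen(1, "iv_bolus")),
               "K_cell_pls_fetal")
  expect_error(placenta_physiology(Q_placenta = 0), "Q_placenta")
  expect_error(plasma_composition(f_water_pls = 1.2), "f_water_pls")
  expect_error(maternal_config(F = 0), "'F'")
  expect_error(maternal_config(CO = 5), "cardiac output")
})

test_that("unit conversions are applied on load", {
  p <- placenta_physiology(SA_int_cell_dm2 = 56700)
  expect_equal(p$SA_int_cell_cm2, 5.67e6)
  ev <- dosing_events(dose_regimen(500, "iv_bolus"), 171.15)
  expect_equal(ev$bolus$amount_umol, 500 / 171.15 * 1000)
})

test_that("minimal config pulls library values and explicit overrides win", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("drug:\n  name: metronidazole\n", path)
  cfg <- load_config(path)
  expect_equal(cfg$drug$fu_maternal, 0.92)
  expect_equal(cfg$drug$CL_apical, 9.76)
  expect_equal(cfg$placenta$f_out, 1)
  expect_equal(cfg$placenta$Q_placenta, 0.75)

  writeLines(c("drug:", "  name: metronidazole", "placenta:",
               "  f_out: 0.5"), path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$placenta$f_out, 0.5)
  expect_equal(cfg2$placenta$f_in, 1)
  expect_equal(cfg2$drug$CL_apical, 9.76)

  writeLines(c("drug:", "  name: metronidazole", "  fu_maternal: 1.3"),
             path)
  expect_error(load_config(path), "fu_maternal")
  expect_error(load_config("no/such/file.yaml"), "not found")
  writeLines("placenta:\n  f_in: 2\n", path)
  expect_error(load_config(path), "drug.name")
})

test_that("config files round-trip to an identical bundle", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("drug:", "  name: diazepam", "placenta:", "  f_in: 1.5",
               "  g_out: 0.8", "maternal:", "  CL_hepatic: 0.5"), path)
  bundle <- load_config(path)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(bundle, path2)
  bundle2 <- load_config(path2)
  expect_equal(bundle2, bundle)
})
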