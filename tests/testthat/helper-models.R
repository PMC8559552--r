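# shared fixtures, built in code

# a drug with unremarkable parameters for property-style tests
test_drug <- function(fu_fetal = 0.4, fu_maternal = 0.5, K_cell = 0.8,
                      CL_apical = 1, P_baso = 1e-3) {
  drug_parameters(
    name = "probe", fu_nonpreg = 0.45, fu_maternal = fu_maternal,
    fu_fetal = fu_fetal, K_apical = K_cell, K_cell_pls_fetal = K_cell,
    CL_apical = CL_apical, P_basolateral = P_baso, molecular_weight = 300,
    regimen = dose_regimen(100, "iv_bolus"))
}

random_geometry <- function() {
  compartment_geometry(
    V_bc = runif(1, 0.01, 0.5), V_pls = runif(1, 0.01, 0.5),
    V_int = runif(1, 0.05, 1), V_cell = runif(1, 0.1, 3),
    SA_bc = runif(1, 1e3, 1e5), SA_end = runif(1, 1e3, 1e5),
    SA_int_cell = runif(1, 1e4, 1e7),
    P_pls_bc = runif(1, 1e-4, 1e-1), P_end = runif(1, 1e-4, 1e-1),
    P_int_cell = runif(1, 1e-6, 1e-1), Q = runif(1, 0.05, 1))
}

random_drug <- function() {
  fu_m <- runif(1, 0.005, 1)
  test_drug(fu_fetal = runif(1, 0.005, 1), fu_maternal = fu_m,
            K_cell = runif(1, 0.05, 5), CL_apical = runif(1, 0.01, 10),
            P_baso = runif(1, 1e-6, 1e-1))
}

# maternal core without elimination, for closed-system checks
closed_maternal <- function(name) {
  m <- maternal_defaults(name)
  maternal_config(Kp = m$Kp, CL_hepatic = 0, CL_renal = 0, ka = m$ka,
                  F = 1)
}
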