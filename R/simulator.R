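# Model assembly and ODE integration.
#
# The coupled maternal + placental + fetal system is linear in the state
# (amounts, umol). The maternal core drives the trophoblast through the
# apical flux; the fetal side is a closed perfusion loop
# fetus -> umbilical artery -> fetal placenta -> umbilical vein -> fetus,
# with each organ compartment resolved into (bc, pls, int, cell)
# sub-compartments exchanging through a conservative 4x4 matrix. The
# amniotic fluid pool exchanges with nothing. The state is integrated in
# amounts so that mass conservation is a literal sum; concentrations are
# derived on output.

state_names <- c(
  "m_ven", "m_art", "m_lung", "m_liver", "m_kidney", "m_rest", "m_plac",
  "m_depot",
  "pl_bc", "pl_pls", "pl_int", "pl_cell",
  "fe_bc", "fe_pls", "fe_int", "fe_cell",
  "ua_bc", "ua_pls", "uv_bc", "uv_pls",
  "amn", "elim", "unabs")

#' Construct a maternal-fetal PBPK model
#'
#' Assembles a drug, the placenta physiology, plasma composition, fetal
#' geometry and the reduced maternal core into a simulation-ready model
#' object. Use [simulate()] on the result for a single individual,
#' [simulate_population()] for a virtual population, [compare_fu()] for the
#' equal-vs-different fraction unbound comparison and [run_sensitivity()]
#' for local sensitivity sweeps.
#'
#' @param drug a [drug_parameters()] object or the name of a library drug.
#' @param placenta a [placenta_physiology()].
#' @param plasma a [plasma_composition()].
#' @param geometry a [fetal_geometry()].
#' @param maternal a [maternal_config()]; defaults to [maternal_defaults()]
#'   for the drug.
#' @param exchange `"fetal_fu"` for the fetus-specific-binding exchange
#'   matrices (the default), `"legacy"` for the single-fu formulation.
#' @param maternal_mode `"dynamic"` (full maternal core) or `"constant"`
#'   (maternal placental plasma held at `const_maternal_conc`, maternal
#'   states frozen; used for equilibrium-ratio analyses).
#' @param const_maternal_conc maternal placental plasma concentration,
#'   umol/L, when `maternal_mode = "constant"`.
#' @return An object of class `"pbpk_model"`.
#' @examples
#' mod <- pbpk_model("metronidazole")
#' sim <- simulate(mod, tmax_h = 12, dt_min = 5)
#' @export
pbpk_model <- function(drug, placenta = placenta_physiology(),
                       plasma = plasma_composition(),
                       geometry = fetal_geometry(),
                       maternal = NULL,
                       exchange = c("fetal_fu", "legacy"),
                       maternal_mode = c("dynamic", "constant"),
                       const_maternal_conc = NA_real_) {
  if (is.character(drug)) drug <- get_drug(drug)
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(placenta, "placenta_physiology"),
            inherits(plasma, "plasma_composition"),
            inherits(geometry, "fetal_geometry"))
  exchange <- match.arg(exchange)
  maternal_mode <- match.arg(maternal_mode)
  if (is.null(maternal)) maternal <- maternal_defaults(drug$name)
  stopifnot(inherits(maternal, "maternal_config"))
  if (maternal_mode == "constant" && !is.finite(const_maternal_conc)) {
    stop("pbpk_model: 'const_maternal_conc' required for constant mode",
         call. = FALSE)
  }
  # keep the maternal core's placental flow in step with the physiology;
  # the difference is redistributed to rest-of-body so cardiac output (and
  # with it maternal kinetics) is unchanged by placental-flow perturbations
  if (abs(maternal$Q_placenta - placenta$Q_placenta) > 1e-12) {
    dq <- placenta$Q_placenta - maternal$Q_placenta
    if (maternal$Q_rest - dq <= 0) {
      stop("pbpk_model: placental flow exceeds the flow available for ",
           "redistribution from rest-of-body", call. = FALSE)
    }
    maternal <- maternal_config(
      V_ven = maternal$V_ven, V_art = maternal$V_art,
      V_lung = maternal$V_lung, V_liver = maternal$V_liver,
      V_kidney = maternal$V_kidney, V_rest = maternal$V_rest,
      V_placenta = maternal$V_placenta, CO = maternal$CO,
      Q_liver = maternal$Q_liver, Q_kidney = maternal$Q_kidney,
      Q_rest = maternal$Q_rest - dq, Q_placenta = placenta$Q_placenta,
      Kp = maternal$Kp, CL_hepatic = maternal$CL_hepatic,
      CL_renal = maternal$CL_renal, ka = maternal$ka, F = maternal$F,
      hct_maternal = maternal$hct_maternal)
  }

  geom_pl <- geometry$placenta
  geom_pl$SA_int_cell <- placenta$SA_int_cell_cm2
  builder <- if (exchange == "legacy") legacy_exchange_matrix
             else build_exchange_matrix
  E_fe <- builder(geometry$fetus, drug, plasma)
  E_pl <- builder(geom_pl, drug, plasma, g_in = placenta$g_in,
                  g_out = placenta$g_out)

  structure(
    list(drug = drug, placenta = placenta, plasma = plasma,
         geometry = geometry, maternal = maternal, exchange = exchange,
         maternal_mode = maternal_mode,
         const_maternal_conc = const_maternal_conc,
         E_fe = E_fe, E_pl = E_pl,
         a_in = placenta$f_in * drug$CL_apical * drug$fu_maternal,
         a_out = placenta$f_out * drug$CL_apical * drug$fu_maternal /
           drug$K_apical),
    class = "pbpk_model")
}

# volume vector matching state_names (depot and bookkeeping states get
# volume 1; their "concentration" is never used)
model_volumes <- function(model) {
  m <- model$maternal
  g <- model$geometry
  fe <- g$fetus; pl <- g$placenta
  v <- c(m$V_ven, m$V_art, m$V_lung, m$V_liver, m$V_kidney, m$V_rest,
         m$V_placenta, 1,
         pl$V_bc, pl$V_pls, pl$V_int, pl$V_cell,
         fe$V_bc, fe$V_pls, fe$V_int, fe$V_cell,
         g$V_umb_art, g$V_umb_ven, g$V_umb_ven, g$V_umb_ven,
         g$V_amniotic, 1, 1)
  # umbilical pools: split whole-blood volume by hematocrit
  hct <- model$placenta$hct_fetal
  v[17] <- g$V_umb_art * hct
  v[18] <- g$V_umb_art * (1 - hct)
  v[19] <- g$V_umb_ven * hct
  v[20] <- g$V_umb_ven * (1 - hct)
  names(v) <- state_names
  v
}

model_rhs <- function(t, y, p) {
  C <- y / p$V
  mat <- p$m
  Kp <- mat$Kp
  constant <- p$constant
  C_plM <- if (constant) p$const_conc else C[7L]
  J_ap <- p$a_in * C_plM - p$a_out * C[12L]

  inf_rate <- 0
  if (p$has_inf) {
    act <- p$inf$start <= t & t < p$inf$end
    if (any(act)) inf_rate <- sum(p$inf$rate_umol_min[act])
  }

  d <- numeric(23L)
  if (p$forced) {
    # maternal arterial concentration imposed as an external forcing; only
    # the intervillous compartment and the fetal side evolve
    C_art <- p$C_art_fun(t)
    d[7L] <- mat$Q_placenta * (C_art - C_plM) - J_ap
  } else if (!constant) {
    out_lu <- C[3L] / Kp; out_li <- C[4L] / Kp
    out_ki <- C[5L] / Kp; out_re <- C[6L] / Kp
    d[1L] <- mat$Q_liver * out_li + mat$Q_kidney * out_ki +
      mat$Q_rest * out_re + mat$Q_placenta * C_plM - mat$CO * C[1L] +
      inf_rate
    d[2L] <- mat$CO * (out_lu - C[2L])
    d[3L] <- mat$CO * (C[1L] - out_lu)
    d[4L] <- mat$Q_liver * (C[2L] - out_li) + mat$ka * mat$F * y[8L] -
      p$el_h * out_li
    d[5L] <- mat$Q_kidney * (C[2L] - out_ki) - p$el_r * out_ki
    d[6L] <- mat$Q_rest * (C[2L] - out_re)
    d[7L] <- mat$Q_placenta * (C[2L] - C_plM) - J_ap
    d[8L] <- -mat$ka * y[8L]
    d[22L] <- p$el_h * out_li + p$el_r * out_ki
    d[23L] <- mat$ka * (1 - mat$F) * y[8L]
  } else {
    d[7L] <- 0  # maternal side frozen; barrier driven by const_conc
  }

  Qf <- p$Qf; hct <- p$hct_f
  # fetal placenta, fed by umbilical artery
  Cpl <- C[9:12]
  d[9:12] <- p$E_pl %*% Cpl
  d[9L] <- d[9L] + Qf * hct * (C[17L] - Cpl[1L])
  d[10L] <- d[10L] + Qf * (1 - hct) * (C[18L] - Cpl[2L])
  d[12L] <- d[12L] + J_ap
  # fetus, fed by umbilical vein
  Cfe <- C[13:16]
  d[13:16] <- p$E_fe %*% Cfe
  d[13L] <- d[13L] + Qf * hct * (C[19L] - Cfe[1L])
  d[14L] <- d[14L] + Qf * (1 - hct) * (C[20L] - Cfe[2L])
  # umbilical pools
  d[17L] <- Qf * hct * (Cfe[1L] - C[17L])
  d[18L] <- Qf * (1 - hct) * (Cfe[2L] - C[18L])
  d[19L] <- Qf * hct * (Cpl[1L] - C[19L])
  d[20L] <- Qf * (1 - hct) * (Cpl[2L] - C[20L])
  d[21L] <- 0  # amniotic fluid: isolated
  list(d)
}

model_parms <- function(model) {
  list(V = model_volumes(model), m = model$maternal,
       a_in = model$a_in, a_out = model$a_out,
       el_h = model$maternal$CL_hepatic * model$drug$fu_maternal,
       el_r = model$maternal$CL_renal * model$drug$fu_maternal,
       E_pl = model$E_pl$E, E_fe = model$E_fe$E,
       Qf = model$geometry$Q_umbilical,
       hct_f = model$placenta$hct_fetal,
       constant = model$maternal_mode == "constant",
       const_conc = model$const_maternal_conc,
       forced = FALSE, C_art_fun = NULL,
       has_inf = FALSE,
       inf = data.frame(start = numeric(0), end = numeric(0),
                        rate_umol_min = numeric(0)))
}

# full dosing course on a global time axis: K burn-in intervals (coarse
# grid) followed by one observation window (fine grid), boluses applied at
# each interval start; used by the sensitivity driver, which needs the
# un-rebased trajectory
run_course <- function(model, K, window_min, dt_burn, dt_fine,
                       parms = NULL, dose = TRUE,
                       rtol = 1e-8, atol = 1e-8) {
  if (is.null(parms)) parms <- model_parms(model)
  reg <- model$drug$regimen
  ev <- dosing_events(reg, model$drug$molecular_weight)
  parms$has_inf <- dose && nrow(ev$infusion) > 0
  parms$inf <- ev$infusion
  give <- function(y) {
    if (dose && nrow(ev$bolus) > 0) {
      tgt <- ev$bolus$target[1]
      y[tgt] <- y[tgt] + ev$bolus$amount_umol[1]
    }
    y
  }
  y <- stats::setNames(numeric(23L), state_names)
  L <- if (reg$n_doses > 1) reg$interval_h * 60 else NA_real_
  times <- numeric(0)
  states <- NULL
  t0 <- 0
  if (!is.na(L) && K > 0) {
    for (k in seq_len(K)) {
      y <- give(y)
      out <- integrate_window(y, t0, L, dt_burn, parms, rtol, atol)
      y <- out[nrow(out), 1 + seq_len(23L)]
      times <- c(times, t0 + out[-nrow(out), 1])
      states <- rbind(states, out[-nrow(out), 1 + seq_len(23L)])
      t0 <- t0 + L
    }
  }
  y <- give(y)
  out <- integrate_window(y, t0, window_min, dt_fine, parms, rtol, atol)
  times <- c(times, t0 + out[, 1])
  states <- rbind(states, out[, 1 + seq_len(23L)])
  colnames(states) <- state_names
  list(time_min = times, states = states, window_start = t0)
}

# integrate one window [t0, t0 + span] from state y0 on a local grid
integrate_window <- function(y0, t0, span, dt, parms, rtol, atol) {
  times <- unique(sort(c(seq(0, span, by = dt), span)))
  if (parms$has_inf) {
    bnd <- c(parms$inf$start, parms$inf$end) - t0
    bnd <- bnd[bnd > 0 & bnd < span]
    times <- unique(sort(c(times, bnd)))
  }
  p <- parms
  if (p$has_inf) {
    p$inf$start <- p$inf$start - t0
    p$inf$end <- p$inf$end - t0
  }
  out <- deSolve::lsoda(y = y0, times = times, func = model_rhs, parms = p,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("solver failed to converge; last valid time %.3f min",
                 t0 + max(out[, 1])), call. = FALSE)
  }
  out
}

#' Simulate a single individual
#'
#' Integrates the full maternal + placental + fetal ODE system for the
#' model's dose regimen with a stiff-capable solver. For a single dose the
#' profile covers `[0, tmax_h]`. For a repeated regimen, successive dosing
#' intervals are simulated until the umbilical-vein AUC over one interval
#' changes by less than 1% between consecutive intervals (periodic steady
#' state); the profile of the following interval is returned with time
#' re-based to its dose.
#'
#' @param object a [pbpk_model()].
#' @param nsim number of individuals; `nsim > 1` delegates to
#'   [simulate_population()].
#' @param seed passed to [simulate_population()] when `nsim > 1`.
#' @param tmax_h observation horizon after the (last) dose, hours.
#' @param dt_min output grid resolution, minutes.
#' @param rtol,atol solver tolerances (tolerance-converged defaults).
#' @param dose_scale multiplies every administered amount (linearity
#'   checks; default 1).
#' @param ... unused.
#' @return An object of class `"pbpk_sim"`: list with `time_min`, a
#'   concentration matrix `conc` (ug/mL; columns `maternal_plasma`,
#'   `maternal_placenta`, `umbilical_vein`, `umbilical_artery`,
#'   `fetal_plasma`, `placenta_interstitial`, `trophoblast_cell`), the raw
#'   amount matrix `amounts` (umol), total administered amount, and
#'   steady-state bookkeeping. For `nsim > 1`, a `"pbpk_pop_sim"`.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                tmax_h = 24, dt_min = 1,
                                rtol = 1e-10, atol = 1e-10,
                                dose_scale = 1, ...) {
  if (nsim > 1) {
    return(simulate_population(object, spec = population_spec(
      n = nsim, seed = if (is.null(seed)) 1L else seed),
      tmax_h = tmax_h, dt_min = dt_min, rtol = rtol, atol = atol))
  }
  drug <- object$drug
  reg <- drug$regimen
  parms <- model_parms(object)
  ev <- dosing_events(reg, drug$molecular_weight)
  ev$bolus$amount_umol <- ev$bolus$amount_umol * dose_scale
  ev$infusion$rate_umol_min <- ev$infusion$rate_umol_min * dose_scale
  parms$has_inf <- nrow(ev$infusion) > 0
  parms$inf <- ev$infusion

  y <- stats::setNames(numeric(23L), state_names)
  tmax <- tmax_h * 60
  n_doses <- reg$n_doses
  interval <- if (n_doses > 1) reg$interval_h * 60 else tmax
  apply_dose <- function(y) {
    if (nrow(ev$bolus) > 0) {
      tgt <- ev$bolus$target[1]
      y[tgt] <- y[tgt] + ev$bolus$amount_umol[1]
    }
    y
  }

  ss_doses <- NA_integer_
  if (n_doses == 1L) {
    y <- apply_dose(y)
    out <- integrate_window(y, 0, tmax, dt_min, parms, rtol, atol)
    dose_time <- 0
  } else {
    # burn in to periodic steady state on a coarse grid
    dt_burn <- interval / 200
    auc_prev <- NA_real_
    k <- 0L
    max_doses <- 30L
    repeat {
      k <- k + 1L
      y <- apply_dose(y)
      burn <- integrate_window(y, (k - 1) * interval, interval, dt_burn,
                               parms, rtol, atol)
      y <- burn[nrow(burn), 1 + seq_len(23L)]
      uv <- burn[, "uv_pls"] / parms$V["uv_pls"]
      auc_k <- trapz(burn[, 1], uv)
      converged <- !is.na(auc_prev) && auc_prev > 0 &&
        abs(auc_k - auc_prev) / auc_prev < 0.01
      auc_prev <- auc_k
      if (converged || k >= max_doses) break
    }
    ss_doses <- k
    y <- apply_dose(y)
    out <- integrate_window(y, k * interval, min(tmax, interval), dt_min,
                            parms, rtol, atol)
    dose_time <- k * interval
  }

  amounts <- out[, 1 + seq_len(23L), drop = FALSE]
  colnames(amounts) <- state_names
  if (min(amounts) < -1e-9) {
    warning(sprintf(
      "negative amount excursion (min %.3g umol): treat as solver failure",
      min(amounts)), call. = FALSE)
  }
  V <- parms$V
  ug <- drug$molecular_weight / 1000  # umol/L -> ug/mL
  conc <- cbind(
    maternal_plasma = amounts[, "m_ven"] / V["m_ven"] * ug,
    maternal_placenta = amounts[, "m_plac"] / V["m_plac"] * ug,
    umbilical_vein = amounts[, "uv_pls"] / V["uv_pls"] * ug,
    umbilical_artery = amounts[, "ua_pls"] / V["ua_pls"] * ug,
    fetal_plasma = amounts[, "fe_pls"] / V["fe_pls"] * ug,
    placenta_interstitial = amounts[, "pl_int"] / V["pl_int"] * ug,
    trophoblast_cell = amounts[, "pl_cell"] / V["pl_cell"] * ug)
  if (object$maternal_mode == "constant") {
    conc[, "maternal_plasma"] <- object$const_maternal_conc * ug
    conc[, "maternal_placenta"] <- object$const_maternal_conc * ug
  }
  structure(
    list(time_min = out[, 1], conc = conc, amounts = amounts,
         volumes = V, drug = drug$name,
         molecular_weight = drug$molecular_weight,
         dose_time_min = dose_time, ss_doses = ss_doses,
         dosed_per_admin_umol = if (nrow(ev$bolus)) ev$bolus$amount_umol[1]
                                else NA_real_),
    class = "pbpk_sim")
}

#' Whole-system mass balance of a simulation
#'
#' Total drug amount in every compartment plus the cumulative eliminated
#' and unabsorbed amounts, versus the cumulative administered amount at each
#' output time. For a closed system (no clearances) the relative error is
#' the solver's conservation drift.
#'
#' @param sim a `"pbpk_sim"`.
#' @param dosed_umol total administered amount over the reported window,
#'   umol; defaults to the amount inferred from the simulation.
#' @return data.frame `time_min`, `total_umol`, `rel_error`.
#' @export
mass_balance <- function(sim, dosed_umol = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  total <- rowSums(sim$amounts)
  if (is.null(dosed_umol)) dosed_umol <- total[1]
  data.frame(time_min = sim$time_min, total_umol = total,
             rel_error = (total - dosed_umol) / dosed_umol)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Virtual-population specification
#'
#' @param n number of individuals (default 500).
#' @param cv_map named numeric vector of lognormal coefficients of
#'   variation; recognised names: `CL_hepatic`, `CL_renal`, `Kp`, `ka`,
#'   `Q_placenta`, `CL_apical`.
#' @param seed master integer seed; each individual draws from an
#'   independent stream derived from it, so changing `n` does not reshuffle
#'   earlier individuals.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(n = 500,
                            cv_map = c(CL_hepatic = 0.3, CL_renal = 0.3,
                                       Kp = 0.2, ka = 0.3,
                                       Q_placenta = 0.15, CL_apical = 0.3),
                            seed = 1L) {
  if (n < 1) stop("population_spec: 'n' must be >= 1", call. = FALSE)
  if (any(cv_map < 0)) stop("population_spec: CVs must be >= 0",
                            call. = FALSE)
  structure(list(n = as.integer(n), cv_map = cv_map,
                 seed = as.integer(seed)),
            class = "population_spec")
}

individual_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i) %% 2147483647L)
}

draw_individual <- function(model, cv_map, seed) {
  set.seed(seed)
  ln <- function(med, cv) {
    if (cv <= 0) return(med)
    med * stats::rlnorm(1, 0, sqrt(log(1 + cv^2)))
  }
  cv <- function(nm) if (nm %in% names(cv_map)) cv_map[[nm]] else 0
  m <- model$maternal
  Qp <- ln(m$Q_placenta, cv("Q_placenta"))
  mat <- maternal_config(
    V_ven = m$V_ven, V_art = m$V_art, V_lung = m$V_lung,
    V_liver = m$V_liver, V_kidney = m$V_kidney, V_rest = m$V_rest,
    V_placenta = m$V_placenta, CO = m$CO,
    Q_liver = m$Q_liver, Q_kidney = m$Q_kidney,
    Q_rest = m$Q_rest - (Qp - m$Q_placenta), Q_placenta = Qp,
    Kp = ln(m$Kp, cv("Kp")),
    CL_hepatic = ln(m$CL_hepatic, cv("CL_hepatic")),
    CL_renal = ln(m$CL_renal, cv("CL_renal")),
    ka = ln(m$ka, cv("ka")), F = m$F, hct_maternal = m$hct_maternal)
  d <- model$drug
  d$CL_apical <- ln(d$CL_apical, cv("CL_apical"))
  p <- model$placenta
  pl <- placenta_physiology(
    Q_placenta = Qp, SA_int_cell_dm2 = p$SA_int_cell_dm2,
    f_in = p$f_in, f_out = p$f_out, g_in = p$g_in, g_out = p$g_out,
    hct_maternal = p$hct_maternal, hct_fetal = p$hct_fetal)
  pbpk_model(d, placenta = pl, plasma = model$plasma,
             geometry = model$geometry, maternal = mat,
             exchange = model$exchange)
}

geomean_profile <- function(x) {
  apply(x, 2, function(col) {
    if (any(col <= 0)) 0 else exp(mean(log(col)))
  })
}

#' Simulate a virtual population
#'
#' Runs the model for `spec$n` individuals with independent lognormal
#' parameter variability (one random stream per individual, derived from the
#' master seed) and summarises maternal peripheral plasma and umbilical-vein
#' plasma profiles as pointwise geometric mean and empirical 5th/95th
#' percentiles.
#'
#' @param model a [pbpk_model()].
#' @param spec a [population_spec()].
#' @param tmax_h,dt_min,rtol,atol see [simulate.pbpk_model()].
#' @return An object of class `"pbpk_pop_sim"`: `time_min`, matrices
#'   `maternal_plasma` and `umbilical_vein` (individuals x time, ug/mL),
#'   and a `summary` list with `geomean`, `p5`, `p95` per output.
#' @export
simulate_population <- function(model, spec = population_spec(),
                                tmax_h = 24, dt_min = 1,
                                rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "pbpk_model"), inherits(spec, "population_spec"))
  sims <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    ind <- draw_individual(model, spec$cv_map,
                           individual_seed(spec$seed, i))
    sims[[i]] <- simulate(ind, tmax_h = tmax_h, dt_min = dt_min,
                          rtol = rtol, atol = atol)
  }
  time_min <- sims[[1]]$time_min
  mat <- do.call(rbind, lapply(sims, function(s) s$conc[, "maternal_plasma"]))
  uv <- do.call(rbind, lapply(sims, function(s) s$conc[, "umbilical_vein"]))
  summarise <- function(x) list(
    geomean = geomean_profile(x),
    p5 = apply(x, 2, stats::quantile, probs = 0.05, names = FALSE),
    p95 = apply(x, 2, stats::quantile, probs = 0.95, names = FALSE))
  structure(
    list(time_min = time_min, maternal_plasma = mat, umbilical_vein = uv,
         summary = list(maternal_plasma = summarise(mat),
                        umbilical_vein = summarise(uv)),
         n = spec$n, seed = spec$seed, drug = model$drug$name),
    class = "pbpk_pop_sim")
}

#' Equal vs different maternal-fetal fraction unbound
#'
#' Simulates the model twice -- once with the fetal fraction unbound forced
#' equal to the maternal value, once with the drug's fetal value -- and
#' reports the percent difference in umbilical-vein AUC to the end of the
#' observation window.
#'
#' @param drug a [drug_parameters()] or library drug name.
#' @param tmax_h,dt_min observation window and grid.
#' @param ... passed to [pbpk_model()].
#' @return An object of class `"fu_comparison"`: both `"pbpk_sim"` objects,
#'   the two AUCs (ug h/mL) and `difference_pct`.
#' @export
compare_fu <- function(drug, tmax_h = 24, dt_min = 2, ...) {
  if (is.character(drug)) drug <- get_drug(drug)
  drug_eq <- drug
  drug_eq$fu_fetal <- drug$fu_maternal
  m_diff <- pbpk_model(drug, ...)
  m_eq <- pbpk_model(drug_eq, ...)
  s_diff <- simulate(m_diff, tmax_h = tmax_h, dt_min = dt_min)
  s_eq <- simulate(m_eq, tmax_h = tmax_h, dt_min = dt_min)
  auc_eq <- auc_tlast(s_eq$time_min / 60, s_eq$conc[, "umbilical_vein"])
  auc_diff <- auc_tlast(s_diff$time_min / 60,
                        s_diff$conc[, "umbilical_vein"])
  structure(
    list(drug = drug$name, sim_equal = s_eq, sim_different = s_diff,
         auc_equal = auc_eq, auc_different = auc_diff,
         difference_pct = percent_difference(auc_eq, auc_diff)),
    class = "fu_comparison")
}

#' @export
print.fu_comparison <- function(x, ...) {
  cat(sprintf("%s: umbilical-vein AUC_tlast %.3g (equal fu) vs %.3g (fetal fu) ug h/mL; difference %+.1f%%\n",
              x$drug, x$auc_equal, x$auc_different, x$difference_pct))
  invisible(x)
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s (%s exchange, %s maternal core)\n",
              x$drug$name, x$exchange, x$maternal_mode))
  r <- x$drug$regimen
  cat(sprintf("  regimen: %g mg %s x%d%s\n", r$dose_mg, r$route, r$n_doses,
              if (!is.na(r$interval_h)) sprintf(" q%gh", r$interval_h)
              else ""))
  cat(sprintf("  barrier: CL_apical %.3g L/min (f_in %.3g, f_out %.3g), CL_basolateral %.3g L/min (g_in %.3g, g_out %.3g)\n",
              x$drug$CL_apical, x$placenta$f_in, x$placenta$f_out,
              basolateral_clearance(x$drug$P_basolateral,
                                    x$placenta$SA_int_cell_dm2),
              x$placenta$g_in, x$placenta$g_out))
  d <- flow_limitation_diagnostic(x$drug, x$placenta$Q_placenta)
  cat(sprintf("  placental distribution: %s (fu x CL_apical = %.3g L/min)\n",
              d$regime, d$product))
  invisible(x)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  ratios <- equilibrium_concentration_ratios(object$drug, object$plasma)
  out <- list(
    drug = object$drug$name,
    diagnostic = flow_limitation_diagnostic(object$drug,
                                            object$placenta$Q_placenta),
    equilibrium_ratios = ratios,
    quasi_equilibrium_fetal_maternal =
      object$drug$fu_maternal / object$drug$fu_fetal,
    coef = coef(object))
  class(out) <- "summary.pbpk_model"
  out
}

#' @export
print.summary.pbpk_model <- function(x, ...) {
  cat(sprintf("Maternal-fetal PBPK model: %s\n", x$drug))
  print(x$diagnostic)
  cat(sprintf("  zero-flux ratios: C_int/C_pls %.3g, C_cell/C_pls %.3g\n",
              x$equilibrium_ratios["int_pls"],
              x$equilibrium_ratios["cell_pls"]))
  cat(sprintf("  quasi-equilibrium fetal:maternal plasma ratio (fu_M/fu_F): %.3g\n",
              x$quasi_equilibrium_fetal_maternal))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  d <- object$drug
  p <- object$placenta
  c(fu_nonpreg = d$fu_nonpreg, fu_maternal = d$fu_maternal,
    fu_fetal = d$fu_fetal, K_apical = d$K_apical,
    K_cell_pls_fetal = d$K_cell_pls_fetal, CL_apical = d$CL_apical,
    P_basolateral = d$P_basolateral, K_bc = d$K_bc,
    molecular_weight = d$molecular_weight, Q_placenta = p$Q_placenta,
    f_in = p$f_in, f_out = p$f_out, g_in = p$g_in, g_out = p$g_out)
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s: %d time points over %.3g h\n", x$drug,
              length(x$time_min), max(x$time_min) / 60))
  auc <- auc_tlast(x$time_min / 60, x$conc[, "umbilical_vein"])
  cat(sprintf("  umbilical-vein AUC_tlast %.4g ug h/mL; Cmax maternal %.4g, umbilical %.4g ug/mL\n",
              auc, max(x$conc[, "maternal_plasma"]),
              max(x$conc[, "umbilical_vein"])))
  if (!is.na(x$ss_doses)) {
    cat(sprintf("  periodic steady state after %d doses; profile re-based to the following dose\n",
                x$ss_doses))
  }
  invisible(x)
}

#' @export
as.data.frame.pbpk_sim <- function(x, ...) {
  cc <- x$conc
  data.frame(
    time_min = rep(x$time_min, ncol(cc)),
    compartment = rep(colnames(cc), each = nrow(cc)),
    concentration_ug_per_mL = as.vector(cc),
    stringsAsFactors = FALSE)
}

#' @export
plot.pbpk_sim <- function(x, compartments = c("maternal_plasma",
                                              "umbilical_vein"),
                          log = "", ...) {
  cc <- x$conc[, compartments, drop = FALSE]
  t_h <- x$time_min / 60
  graphics::matplot(t_h, cc, type = "l", lty = 1,
                    col = seq_len(ncol(cc)) + 1,
                    xlab = "time after dose (h)",
                    ylab = "concentration (ug/mL)", log = log,
                    main = x$drug, ...)
  graphics::legend("topright", legend = compartments, lty = 1,
                   col = seq_len(ncol(cc)) + 1, bty = "n")
  invisible(x)
}

#' @export
plot.pbpk_pop_sim <- function(x, output = c("umbilical_vein",
                                            "maternal_plasma"), ...) {
  output <- match.arg(output)
  s <- x$summary[[output]]
  t_h <- x$time_min / 60
  graphics::plot(t_h, s$geomean, type = "n",
                 ylim = range(c(s$p5, s$p95)),
                 xlab = "time after dose (h)",
                 ylab = "concentration (ug/mL)",
                 main = sprintf("%s, %s (n = %d)", x$drug, output, x$n), ...)
  graphics::polygon(c(t_h, rev(t_h)), c(s$p5, rev(s$p95)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(t_h, s$geomean, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' @export
print.pbpk_pop_sim <- function(x, ...) {
  cat(sprintf("<pbpk_pop_sim> %s: n = %d individuals, seed %d\n", x$drug,
              x$n, x$seed))
  gm <- x$summary$umbilical_vein$geomean
  auc <- auc_tlast(x$time_min / 60, gm)
  cat(sprintf("  geomean umbilical-vein AUC_tlast %.4g ug h/mL\n", auc))
  invisible(x)
}
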