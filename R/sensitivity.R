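# Local sensitivity driver for placental-transfer parameters.
#
# One target parameter per run: maternal placental blood flow, the apical
# scaling factors jointly or one-sided, or the basolateral transfer
# clearance. Deltas are computed on the umbilical-vein AUC_tlast of a
# deterministic single-individual simulation; maternal output is
# deliberately not reported.

sensitivity_targets <- c("placental_blood_flow", "apical_joint",
                         "apical_influx_only", "apical_efflux_only",
                         "basolateral_joint")

default_factor_grids <- list(
  placental_blood_flow = c(0.5, 2),
  apical_joint = c(2, 5, 10),
  apical_influx_only = c(0.5, 0.75, 1.5, 2),
  apical_efflux_only = c(0.5, 0.75, 1.5, 2),
  basolateral_joint = c(1.5, 2, 5, 10))

#' Sensitivity-analysis plan
#'
#' One target parameter and a grid of positive multipliers. Default grids:
#' `{0.5, 2}` for placental blood flow, `{2, 5, 10}` for the joint apical
#' sweep, `{0.5, 0.75, 1.5, 2}` for one-sided apical sweeps, and
#' `{1.5, 2, 5, 10}` for the basolateral clearance.
#'
#' @param target one of `"placental_blood_flow"`, `"apical_joint"`,
#'   `"apical_influx_only"`, `"apical_efflux_only"`, `"basolateral_joint"`.
#' @param factors positive multipliers; defaults per target.
#' @return An object of class `"sensitivity_plan"`.
#' @export
sensitivity_plan <- function(target = sensitivity_targets, factors = NULL) {
  target <- match.arg(target)
  if (is.null(factors)) factors <- default_factor_grids[[target]]
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("sensitivity_plan: factors must be positive", call. = FALSE)
  }
  structure(list(target = target, factors = factors),
            class = "sensitivity_plan")
}

apply_factor <- function(model, target, f) {
  p <- model$placenta
  args <- list(drug = model$drug, plasma = model$plasma,
               geometry = model$geometry, exchange = model$exchange,
               maternal = model$maternal)
  newp <- switch(
    target,
    placental_blood_flow = placenta_physiology(
      Q_placenta = p$Q_placenta * f, SA_int_cell_dm2 = p$SA_int_cell_dm2,
      f_in = p$f_in, f_out = p$f_out, g_in = p$g_in, g_out = p$g_out,
      hct_maternal = p$hct_maternal, hct_fetal = p$hct_fetal),
    apical_joint = placenta_physiology(
      Q_placenta = p$Q_placenta, SA_int_cell_dm2 = p$SA_int_cell_dm2,
      f_in = p$f_in * f, f_out = p$f_out * f, g_in = p$g_in,
      g_out = p$g_out, hct_maternal = p$hct_maternal,
      hct_fetal = p$hct_fetal),
    apical_influx_only = placenta_physiology(
      Q_placenta = p$Q_placenta, SA_int_cell_dm2 = p$SA_int_cell_dm2,
      f_in = p$f_in * f, f_out = p$f_out, g_in = p$g_in, g_out = p$g_out,
      hct_maternal = p$hct_maternal, hct_fetal = p$hct_fetal),
    apical_efflux_only = placenta_physiology(
      Q_placenta = p$Q_placenta, SA_int_cell_dm2 = p$SA_int_cell_dm2,
      f_in = p$f_in, f_out = p$f_out * f, g_in = p$g_in, g_out = p$g_out,
      hct_maternal = p$hct_maternal, hct_fetal = p$hct_fetal),
    basolateral_joint = placenta_physiology(
      Q_placenta = p$Q_placenta, SA_int_cell_dm2 = p$SA_int_cell_dm2,
      f_in = p$f_in, f_out = p$f_out, g_in = p$g_in * f,
      g_out = p$g_out * f, hct_maternal = p$hct_maternal,
      hct_fetal = p$hct_fetal))
  args$placenta <- newp
  do.call(pbpk_model, args)
}

#' Run a local sensitivity sweep
#'
#' Simulates one deterministic individual per factor (the factor 1 baseline
#' is always included) and reports the umbilical-vein AUC from the (last)
#' dose to the end of the observation window, together with the percent
#' change versus baseline. Because placental-transfer parameters have a
#' negligible effect on maternal concentrations, the maternal arterial
#' profile is computed once from the unperturbed model and imposed as a
#' common forcing on every sweep member, so the reported deltas isolate the
#' placental-fetal response; maternal output is not reported. A failed
#' member simulation is reported with a failure flag and `NA` results
#' rather than aborting the sweep.
#'
#' @param model a [pbpk_model()] (the unperturbed baseline).
#' @param plan a [sensitivity_plan()].
#' @param tmax_h observation window after the last dose, hours; defaults to
#'   the drug's `tlast_h` (the span of the clinical sampling the evaluation
#'   mirrors). For repeated regimens the window is capped at one dosing
#'   interval.
#' @param dt_min output grid of the observation window, minutes.
#' @return An object of class `"sensitivity_result"`: a data.frame with
#'   columns `target`, `factor`, `auc_tlast`, `delta_pct`, `failed`;
#'   umbilical-vein profiles attached as attribute `"profiles"`.
#' @export
run_sensitivity <- function(model, plan, tmax_h = NULL, dt_min = 2) {
  stopifnot(inherits(model, "pbpk_model"),
            inherits(plan, "sensitivity_plan"))
  if (is.null(tmax_h)) tmax_h <- model$drug$tlast_h
  reg <- model$drug$regimen
  window <- tmax_h * 60
  K <- 0L
  dt_burn <- window
  if (reg$n_doses > 1L) {
    base_sim <- simulate(model, tmax_h = tmax_h,
                         dt_min = reg$interval_h * 60 / 100)
    K <- base_sim$ss_doses
    window <- min(window, reg$interval_h * 60)
    dt_burn <- reg$interval_h * 60 / 100
  }
  base_course <- run_course(model, K, window, dt_burn, dt_min, dose = TRUE)
  V <- model_volumes(model)
  C_art_fun <- stats::approxfun(base_course$time_min,
                                base_course$states[, "m_art"] / V["m_art"],
                                rule = 2, ties = "ordered")
  ug <- model$drug$molecular_weight / 1000

  run_member <- function(m) {
    parms <- model_parms(m)
    parms$forced <- TRUE
    parms$C_art_fun <- C_art_fun
    course <- run_course(m, K, window, dt_burn, dt_min, parms = parms,
                         dose = FALSE)
    keep <- course$time_min >= course$window_start
    t_h <- (course$time_min[keep] - course$window_start) / 60
    uv <- course$states[keep, "uv_pls"] / V["uv_pls"] * ug
    list(auc = auc_tlast(t_h, uv),
         profile = cbind(time_min = t_h * 60, umbilical_vein = uv))
  }

  factors <- sort(unique(c(1, plan$factors)))
  profiles <- list()
  auc <- rep(NA_real_, length(factors))
  failed <- logical(length(factors))
  for (i in seq_along(factors)) {
    res <- tryCatch(
      run_member(apply_factor(model, plan$target, factors[i])),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
    } else {
      auc[i] <- res$auc
      profiles[[as.character(factors[i])]] <- res$profile
    }
  }
  base <- auc[factors == 1]
  out <- data.frame(target = plan$target, factor = factors,
                    auc_tlast = auc,
                    delta_pct = 100 * (auc - base) / base,
                    failed = failed)
  attr(out, "profiles") <- profiles
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep: %s\n", x$target[1]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
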