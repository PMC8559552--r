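# Reduced maternal whole-body PBPK core.
#
# This is deliberately NOT a published pregnancy model: it is a configurable
# perfusion-limited whole-body core (venous and arterial blood, lung, liver,
# kidney, rest-of-body, intervillous placenta, plus a gut-lumen depot for
# oral dosing) whose role is to supply a maternal placental plasma
# concentration of the right order of magnitude to drive the barrier.
# Per-drug Kp/CL defaults give maternal half-life and Cmax of the right
# order; everything downstream that depends on maternal kinetics is
# evaluated through properties, not concentration values.

#' Maternal whole-body model configuration
#'
#' @param V_ven,V_art,V_lung,V_liver,V_kidney,V_rest,V_placenta compartment
#'   volumes, L (the placenta volume is the maternal intervillous blood
#'   space).
#' @param CO cardiac output, L/min; must equal the sum of the tissue flows.
#' @param Q_liver,Q_kidney,Q_rest,Q_placenta tissue blood flows, L/min.
#' @param Kp uniform tissue : plasma partition coefficient applied to lung,
#'   liver, kidney and rest-of-body.
#' @param CL_hepatic,CL_renal linear clearances, L/min, applied to the
#'   unbound organ-outflow concentration of liver and kidney.
#' @param ka first-order absorption rate constant, 1/min (oral).
#' @param F oral bioavailability, in (0, 1].
#' @param hct_maternal maternal hematocrit (carried for completeness; the
#'   reduced core treats blood as plasma).
#' @return An object of class `"maternal_config"`.
#' @export
maternal_config <- function(V_ven = 3.4, V_art = 1.7, V_lung = 0.5,
                            V_liver = 1.7, V_kidney = 0.3, V_rest = 55,
                            V_placenta = 0.4, CO = 6,
                            Q_liver = 1.5, Q_kidney = 1.2, Q_rest = 2.55,
                            Q_placenta = 0.75, Kp = 1,
                            CL_hepatic = 0, CL_renal = 0,
                            ka = 0.02, F = 1, hct_maternal = 0.39) {
  vols <- c(V_ven = V_ven, V_art = V_art, V_lung = V_lung,
            V_liver = V_liver, V_kidney = V_kidney, V_rest = V_rest,
            V_placenta = V_placenta)
  for (f in names(vols)) {
    if (!is.finite(vols[[f]]) || vols[[f]] <= 0) {
      stop(sprintf("maternal_config: '%s' must be > 0", f), call. = FALSE)
    }
  }
  flows <- c(CO = CO, Q_liver = Q_liver, Q_kidney = Q_kidney,
             Q_rest = Q_rest, Q_placenta = Q_placenta)
  for (f in names(flows)) {
    if (!is.finite(flows[[f]]) || flows[[f]] <= 0) {
      stop(sprintf("maternal_config: '%s' must be > 0", f), call. = FALSE)
    }
  }
  if (abs(CO - (Q_liver + Q_kidney + Q_rest + Q_placenta)) > 1e-9 * CO) {
    stop("maternal_config: tissue flows must sum to cardiac output 'CO'",
         call. = FALSE)
  }
  if (Kp <= 0) stop("maternal_config: 'Kp' must be > 0", call. = FALSE)
  if (CL_hepatic < 0 || CL_renal < 0) {
    stop("maternal_config: clearances must be >= 0", call. = FALSE)
  }
  if (!is.finite(F) || F <= 0 || F > 1) {
    stop("maternal_config: 'F' must be in (0, 1]", call. = FALSE)
  }
  if (ka < 0) stop("maternal_config: 'ka' must be >= 0", call. = FALSE)
  structure(
    list(V_ven = V_ven, V_art = V_art, V_lung = V_lung, V_liver = V_liver,
         V_kidney = V_kidney, V_rest = V_rest, V_placenta = V_placenta,
         CO = CO, Q_liver = Q_liver, Q_kidney = Q_kidney, Q_rest = Q_rest,
         Q_placenta = Q_placenta, Kp = Kp, CL_hepatic = CL_hepatic,
         CL_renal = CL_renal, ka = ka, F = F, hct_maternal = hct_maternal),
    class = "maternal_config")
}

# Per-drug maternal defaults. Order-of-magnitude literature values for
# distribution volume (through a uniform Kp), elimination clearances, and
# oral absorption; documented in the vignette.
maternal_default_table <- function() {
  data.frame(
    name = c("acyclovir", "cefuroxime", "diazepam", "dolutegravir",
             "emtricitabine", "metronidazole", "ondansetron", "raltegravir"),
    Kp = c(0.80, 0.25, 1.40, 0.22, 1.70, 0.72, 2.80, 1.50),
    CL_hepatic = c(0.05, 0.02, 0.95, 1.90, 0.02, 0.065, 1.35, 2.60),
    CL_renal = c(0.30, 0.25, 0.00, 0.00, 0.25, 0.017, 0.00, 0.00),
    ka = c(0.010, 0.020, 0.020, 0.015, 0.020, 0.020, 0.020, 0.008),
    F = c(0.20, 1.00, 1.00, 0.80, 0.93, 1.00, 0.60, 0.32),
    stringsAsFactors = FALSE)
}

#' Default maternal configuration for a library drug
#'
#' Returns a [maternal_config()] whose uniform tissue partition coefficient
#' and hepatic/renal clearances give a maternal plasma half-life and peak
#' concentration of the right order for the named drug. These are package
#' defaults, not the published pregnancy parameterisations.
#'
#' Because elimination acts on the unbound organ-outflow concentration, the
#' tabulated clearances are unbound-referenced values (approximately the
#' plasma clearance divided by the maternal fraction unbound).
#'
#' @param name drug name.
#' @return A `"maternal_config"`.
#' @export
maternal_defaults <- function(name) {
  tab <- maternal_default_table()
  i <- match(name, tab$name)
  if (is.na(i)) return(maternal_config())
  maternal_config(Kp = tab$Kp[i], CL_hepatic = tab$CL_hepatic[i],
                  CL_renal = tab$CL_renal[i], ka = tab$ka[i], F = tab$F[i])
}

#' Dosing event schedule
#'
#' Expands a [dose_regimen()] into a schedule of integrator events: an IV
#' bolus adds `dose_mg / MW * 1000` umol to the maternal venous blood at
#' each dose time; an oral dose adds the same amount to the gut-lumen
#' depot; an infusion is represented as a constant-rate window.
#'
#' @param regimen a [dose_regimen()].
#' @param molecular_weight g/mol.
#' @return A list with `bolus` (data.frame `time`, `amount_umol`, `target`
#'   in `{"m_ven", "m_depot"}`) and `infusion` (data.frame `start`, `end`,
#'   `rate_umol_min`), times in minutes.
#' @examples
#' dosing_events(dose_regimen(500, "iv_bolus"), 171.15)
#' @export
dosing_events <- function(regimen, molecular_weight) {
  stopifnot(inherits(regimen, "dose_regimen"), molecular_weight > 0)
  dose_umol <- regimen$dose_mg / molecular_weight * 1000
  times <- (seq_len(regimen$n_doses) - 1) *
    (if (regimen$n_doses > 1) regimen$interval_h * 60 else 0)
  if (regimen$route == "iv_infusion") {
    dur <- regimen$infusion_duration_min
    list(bolus = data.frame(time = numeric(0), amount_umol = numeric(0),
                            target = character(0)),
         infusion = data.frame(start = times, end = times + dur,
                               rate_umol_min = dose_umol / dur))
  } else {
    target <- if (regimen$route == "iv_bolus") "m_ven" else "m_depot"
    list(bolus = data.frame(time = times, amount_umol = dose_umol,
                            target = target, stringsAsFactors = FALSE),
         infusion = data.frame(start = numeric(0), end = numeric(0),
                               rate_umol_min = numeric(0)))
  }
}
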