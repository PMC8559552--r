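# Apical and basolateral trophoblast transfer, clearance derivations, and
# the flow- vs permeability-limitation diagnostic.

#' Apical transfer flux across the trophoblast membrane
#'
#' Net flux from maternal placental plasma into the trophoblast
#' intracellular space (umol/min, maternal-to-fetal positive):
#' \deqn{J = f_{in} CL_{ap} fu_M C_{pls,M} - f_{out} CL_{ap} fu_M
#'   C_{cell,F} / K_{apical}.}
#' The maternal fraction unbound applies to both directions; the fetal-side
#' binding asymmetry enters the model through the basolateral coefficients,
#' not here. `f_in` and `f_out` different from 1 emulate asymmetric
#' (transporter-like) transfer.
#'
#' @param C_pls_M maternal placental plasma concentration, umol/L.
#' @param C_cell_F trophoblast intracellular concentration, umol/L.
#' @param CL_apical apical transfer clearance, L/min.
#' @param fu_maternal maternal fraction unbound.
#' @param K_apical maternal plasma : trophoblast intracellular partition
#'   coefficient.
#' @param f_in,f_out influx/efflux scaling factors.
#' @return Net apical flux, umol/min.
#' @export
apical_flux <- function(C_pls_M, C_cell_F, CL_apical, fu_maternal,
                        K_apical, f_in = 1, f_out = 1) {
  if (CL_apical < 0) stop("apical_flux: 'CL_apical' must be >= 0",
                          call. = FALSE)
  if (K_apical <= 0) stop("apical_flux: 'K_apical' must be > 0",
                          call. = FALSE)
  f_in * CL_apical * fu_maternal * C_pls_M -
    f_out * CL_apical * fu_maternal * C_cell_F / K_apical
}

#' Basolateral transfer flux across the trophoblast membrane
#'
#' Net flux from the fetal interstitial space of the placenta into the
#' trophoblast intracellular space (umol/min, interstitial-to-cell
#' positive), with each direction independently scalable:
#' \deqn{J = g_{in} P SA \frac{fu_{fetal}}{K_{int,pls}} C_{int}
#'   - g_{out} P SA \frac{fu_{maternal}}{K_{cell,pls}} C_{cell}.}
#'
#' @param C_int,C_cell interstitial and intracellular concentrations,
#'   umol/L.
#' @param P_int_cell basolateral permeability, cm/min.
#' @param SA_int_cell basolateral surface area, cm2.
#' @param fu_fetal,fu_maternal fractions unbound.
#' @param K_int_pls interstitial : plasma partition coefficient (see
#'   [k_int_pls()]).
#' @param K_cell_pls fetal intracellular : plasma partition coefficient.
#' @param g_in,g_out basolateral influx/efflux scaling factors.
#' @return Net basolateral flux, umol/min.
#' @export
basolateral_flux <- function(C_int, C_cell, P_int_cell, SA_int_cell,
                             fu_fetal, fu_maternal, K_int_pls, K_cell_pls,
                             g_in = 1, g_out = 1) {
  if (P_int_cell < 0 || SA_int_cell < 0) {
    stop("basolateral_flux: permeability and surface area must be >= 0",
         call. = FALSE)
  }
  cl <- P_int_cell * SA_int_cell / 1000  # cm3/min -> L/min
  g_in * cl * (fu_fetal / K_int_pls) * C_int -
    g_out * cl * (fu_maternal / K_cell_pls) * C_cell
}

#' Basolateral transfer clearance from organ permeability
#'
#' Product of the drug's organ permeability and the surface area between the
#' trophoblast intracellular and interstitial space, converted to L/min.
#'
#' @param P_int_cell organ permeability, cm/min.
#' @param SA_int_cell_dm2 surface area, dm2 (default 56,700).
#' @return Clearance, L/min.
#' @examples
#' basolateral_clearance(2.73e-6)  # cefuroxime
#' basolateral_clearance(1.69e-2)  # ondansetron
#' @export
basolateral_clearance <- function(P_int_cell, SA_int_cell_dm2 = 56700) {
  if (P_int_cell < 0 || SA_int_cell_dm2 < 0) {
    stop("basolateral_clearance: inputs must be >= 0", call. = FALSE)
  }
  P_int_cell * (SA_int_cell_dm2 * 100) / 1000
}

#' Flow- vs permeability-limitation diagnostic
#'
#' Compares the product of the maternal fraction unbound and the apical
#' transfer clearance with the maternal placental blood flow. When the
#' product exceeds the flow, transplacental distribution is limited by
#' perfusion ("flow_limited"); otherwise by membrane permeability
#' ("permeability_limited").
#'
#' @param drug a [drug_parameters()].
#' @param Q_placenta maternal placental blood flow, L/min.
#' @return A list with `product` (`fu_maternal * CL_apical`, L/min),
#'   `Q_placenta`, and `regime` (one of `"flow_limited"`,
#'   `"permeability_limited"`), class `"flow_diagnostic"`.
#' @examples
#' flow_limitation_diagnostic(get_drug("metronidazole"))
#' @export
flow_limitation_diagnostic <- function(drug, Q_placenta = 0.75) {
  stopifnot(inherits(drug, "drug_parameters"))
  product <- drug$fu_maternal * drug$CL_apical
  structure(
    list(drug = drug$name, product = product, Q_placenta = Q_placenta,
         regime = if (product > Q_placenta) "flow_limited"
                  else "permeability_limited"),
    class = "flow_diagnostic")
}

#' @export
print.flow_diagnostic <- function(x, ...) {
  cat(sprintf("%s: fu_maternal x CL_apical = %.3g L/min vs Q_placenta %.3g L/min -> %s\n",
              x$drug, x$product, x$Q_placenta, x$regime))
  invisible(x)
}

#' Apical transfer clearance by linear calibrator scaling
#'
#' Scales an in vivo apical transfer clearance from in vitro apparent
#' permeability through a user-supplied calibrator drug:
#' `CL = CL_calibrator * Papp_drug / Papp_calibrator`. This is an optional
#' hook; the shipped library carries its apical clearances directly and this
#' function is never invoked silently.
#'
#' @param papp_drug,papp_calibrator apparent permeabilities, cm/s (> 0).
#' @param CL_calibrator calibrator in vivo clearance, L/min.
#' @return Estimated apical transfer clearance, L/min.
#' @export
apical_clearance_from_calibrator <- function(papp_drug, papp_calibrator,
                                             CL_calibrator) {
  if (!is.finite(papp_calibrator) || papp_calibrator <= 0) {
    stop("apical_clearance_from_calibrator: 'papp_calibrator' must be > 0",
         call. = FALSE)
  }
  if (papp_drug <= 0 || CL_calibrator <= 0) {
    stop("apical_clearance_from_calibrator: inputs must be > 0",
         call. = FALSE)
  }
  CL_calibrator * papp_drug / papp_calibrator
}
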