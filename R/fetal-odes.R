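# Passive-exchange right-hand-side assembly for fetal compartments.
#
# Each fetal organ compartment is resolved into four sub-compartments in the
# fixed order (bc, pls, int, cell): blood cells, plasma, interstitial,
# intracellular. Passive gradient-driven exchange is a 4x4 matrix E acting
# on the concentration vector (umol/L) and returning amount rates
# (umol/min); perfusion enters separately through the bc and pls rows only.

sub_order <- c("bc", "pls", "int", "cell")

#' Build the 4x4 passive exchange matrix for a fetal compartment
#'
#' Assembles the exchange matrix `E` mapping the sub-compartment
#' concentration vector (bc, pls, int, cell; umol/L) to passive-exchange
#' amount rates (umol/min). The plasma-blood cell entries use
#' `P_pls_bc * SA_bc` and the blood-cell partition `K_bc`; plasma-
#' interstitial entries use `P_end * SA_end` and the interstitial partition
#' [k_int_pls()] evaluated at the fetal fraction unbound; the
#' interstitial-intracellular (basolateral) entries use
#' `P_int_cell * SA_int_cell` with the interstitial side normalised by
#' `K_int,pls` and the intracellular side carrying the maternal-fu corrected
#' coefficient `fu_maternal / (fu_fetal * K_cell_pls_fetal)`. The whole
#' matrix carries a global `fu_fetal` prefactor. Every column sums to zero:
#' passive exchange conserves mass.
#'
#' Optional basolateral scaling factors `g_in` (interstitial to
#' intracellular) and `g_out` (intracellular to interstitial) scale the two
#' directions of the basolateral membrane independently; both default to 1.
#'
#' @param geom a [compartment_geometry()]. If its `P_int_cell` is `NA` the
#'   drug's `P_basolateral` is used (the trophoblast case).
#' @param drug a [drug_parameters()].
#' @param comp a [plasma_composition()].
#' @param g_in,g_out basolateral influx/efflux scaling factors (>= 0).
#' @param fu_fetal,fu_maternal optional overrides of the drug's fractions
#'   unbound (used for equal-binding comparisons).
#' @return An object of class `"exchange_matrix"`: list with `E` (4x4,
#'   L/min, prefactor applied), `fu_fetal`, and the clearance products used.
#' @export
build_exchange_matrix <- function(geom, drug, comp = plasma_composition(),
                                  g_in = 1, g_out = 1,
                                  fu_fetal = drug$fu_fetal,
                                  fu_maternal = drug$fu_maternal) {
  stopifnot(inherits(geom, "compartment_geometry"),
            inherits(drug, "drug_parameters"))
  if (g_in < 0 || g_out < 0) {
    stop("build_exchange_matrix: scaling factors must be >= 0",
         call. = FALSE)
  }
  K_bc <- drug$K_bc
  K_cell <- drug$K_cell_pls_fetal
  if (K_bc <= 0 || K_cell <= 0) {
    stop("build_exchange_matrix: partition coefficients must be > 0",
         call. = FALSE)
  }
  P_ic <- geom$P_int_cell
  if (is.na(P_ic)) P_ic <- drug$P_basolateral
  K_int <- k_int_pls(fu_fetal, comp)

  # clearance products, cm3/min -> L/min
  cl_bc <- geom$P_pls_bc * geom$SA_bc / 1000
  cl_end <- geom$P_end * geom$SA_end / 1000
  cl_ic <- P_ic * geom$SA_int_cell / 1000

  cell_coef <- fu_maternal / (fu_fetal * K_cell)
  E <- matrix(0, 4, 4, dimnames = list(sub_order, sub_order))
  E["bc", "bc"] <- -cl_bc / K_bc
  E["bc", "pls"] <- cl_bc
  E["pls", "bc"] <- cl_bc / K_bc
  E["pls", "pls"] <- -cl_bc - cl_end
  E["pls", "int"] <- cl_end / K_int
  E["int", "pls"] <- cl_end
  E["int", "int"] <- -cl_end / K_int - g_in * cl_ic / K_int
  E["int", "cell"] <- g_out * cl_ic * cell_coef
  E["cell", "int"] <- g_in * cl_ic / K_int
  E["cell", "cell"] <- -g_out * cl_ic * cell_coef
  E <- fu_fetal * E

  structure(list(E = E, fu_fetal = fu_fetal, fu_maternal = fu_maternal,
                 K_int_pls = K_int, cl_bc = cl_bc, cl_end = cl_end,
                 cl_int_cell = cl_ic),
            class = "exchange_matrix")
}

#' Exchange matrix of the single-fu (pre-update) model
#'
#' Direct implementation of the original passive-exchange equations in which
#' a single (maternal) fraction unbound is used in all fetal compartments:
#' interstitial partition evaluated at the maternal fu and intracellular
#' water coefficient `fu / K_cell,pls` without any correction factor. Used
#' as the reference for the substitution identity `fu_fetal := fu_maternal`.
#'
#' @inheritParams build_exchange_matrix
#' @return An `"exchange_matrix"`.
#' @export
legacy_exchange_matrix <- function(geom, drug, comp = plasma_composition(),
                                   g_in = 1, g_out = 1) {
  fu <- drug$fu_maternal
  P_ic <- geom$P_int_cell
  if (is.na(P_ic)) P_ic <- drug$P_basolateral
  K_int <- k_int_pls(fu, comp)
  cl_bc <- geom$P_pls_bc * geom$SA_bc / 1000
  cl_end <- geom$P_end * geom$SA_end / 1000
  cl_ic <- P_ic * geom$SA_int_cell / 1000

  E <- matrix(0, 4, 4, dimnames = list(sub_order, sub_order))
  E["bc", "bc"] <- -cl_bc / drug$K_bc
  E["bc", "pls"] <- cl_bc
  E["pls", "bc"] <- cl_bc / drug$K_bc
  E["pls", "pls"] <- -cl_bc - cl_end
  E["pls", "int"] <- cl_end / K_int
  E["int", "pls"] <- cl_end
  E["int", "int"] <- -cl_end / K_int - g_in * cl_ic / K_int
  E["int", "cell"] <- g_out * cl_ic / drug$K_cell_pls_fetal
  E["cell", "int"] <- g_in * cl_ic / K_int
  E["cell", "cell"] <- -g_out * cl_ic / drug$K_cell_pls_fetal
  E <- fu * E
  structure(list(E = E, fu_fetal = fu, fu_maternal = fu, K_int_pls = K_int,
                 cl_bc = cl_bc, cl_end = cl_end, cl_int_cell = cl_ic),
            class = "exchange_matrix")
}

#' Amount rates for one fetal compartment
#'
#' Rate of change of the four sub-compartment amounts: perfusion enters the
#' blood-cell and plasma rows only, split by hematocrit, and passive
#' exchange contributes `E %*% C` where concentrations are derived from
#' amounts and sub-volumes.
#'
#' @param amounts numeric length-4 vector of amounts (bc, pls, int, cell),
#'   umol.
#' @param inflow_conc length-2 vector: blood-cell and plasma concentration
#'   of the supplying blood pool, umol/L.
#' @param geom a [compartment_geometry()] (supplies volumes and `Q`).
#' @param E an `"exchange_matrix"` from [build_exchange_matrix()].
#' @param hct hematocrit of the perfusing blood.
#' @return Length-4 vector of amount rates, umol/min.
#' @export
fetal_rhs <- function(amounts, inflow_conc, geom, E, hct) {
  stopifnot(length(amounts) == 4L, length(inflow_conc) == 2L,
            inherits(E, "exchange_matrix"))
  V <- c(geom$V_bc, geom$V_pls, geom$V_int, geom$V_cell)
  if (any(V == 0 & amounts != 0)) {
    stop("fetal_rhs: nonzero amount in a zero-volume sub-compartment",
         call. = FALSE)
  }
  conc <- ifelse(V > 0, amounts / V, 0)
  flow <- c(geom$Q * hct * (inflow_conc[1] - conc[1]),
            geom$Q * (1 - hct) * (inflow_conc[2] - conc[2]), 0, 0)
  as.numeric(flow + E$E %*% conc)
}

#' Zero-flux concentration ratios of the fetal sub-compartments
#'
#' Closed-form equilibrium of the passive-exchange system: at zero net flux
#' the interstitial : plasma ratio is `K_int,pls(fu_fetal)` and the
#' intracellular : plasma ratio is
#' `fu_fetal * K_cell_pls_fetal / fu_maternal`.
#'
#' @param drug a [drug_parameters()].
#' @param comp a [plasma_composition()].
#' @param fu_fetal,fu_maternal optional overrides.
#' @return Named vector `c(int_pls = ..., cell_pls = ..., bc_pls = ...)`.
#' @export
equilibrium_concentration_ratios <- function(drug,
                                             comp = plasma_composition(),
                                             fu_fetal = drug$fu_fetal,
                                             fu_maternal = drug$fu_maternal) {
  c(int_pls = k_int_pls(fu_fetal, comp),
    cell_pls = fu_fetal * drug$K_cell_pls_fetal / fu_maternal,
    bc_pls = drug$K_bc)
}
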