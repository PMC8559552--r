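# Protein-binding and partition-coefficient arithmetic.

#' Estimate the fetal fraction unbound from albumin concentrations
#'
#' Scales the fraction unbound observed in non-pregnant adults to the fetus
#' under linear, single-protein binding: the bound:unbound ratio is
#' proportional to the binding-protein (albumin) concentration, so
#' \deqn{fu_{fetus} = \frac{1}{1 + \frac{1 - fu_{nonpreg}}{C_{prot,nonpreg}
#'   \, fu_{nonpreg}} \, C_{prot,fetus}}.}
#' Implicit assumptions: the drug binds a single plasma protein, and the
#' number of binding sites and the association constant are the same in the
#' adult and the fetus (use [scale_fu_binding_sites()] to relax these).
#'
#' @param fu_nonpreg fraction unbound in non-pregnant adults, in (0, 1].
#' @param Cprot_nonpreg adult binding-protein concentration, g/L.
#' @param Cprot_fetus fetal binding-protein concentration, g/L.
#' @return Fetal fraction unbound, in (0, 1].
#' @examples
#' estimate_fetal_fu(0.020, 46.4, 38.6)
#' @export
estimate_fetal_fu <- function(fu_nonpreg, Cprot_nonpreg, Cprot_fetus) {
  if (any(!is.finite(fu_nonpreg)) || any(fu_nonpreg <= 0) ||
      any(fu_nonpreg > 1)) {
    stop("estimate_fetal_fu: 'fu_nonpreg' must be in (0, 1]", call. = FALSE)
  }
  if (any(Cprot_nonpreg <= 0) || any(Cprot_fetus <= 0)) {
    stop("estimate_fetal_fu: protein concentrations must be > 0",
         call. = FALSE)
  }
  1 / (1 + (1 - fu_nonpreg) / (Cprot_nonpreg * fu_nonpreg) * Cprot_fetus)
}

#' Binding-site parameters for one serum
#'
#' @param n number of binding sites per mole of albumin (dimensionless).
#' @param Ka association constant, 1/M.
#' @param C_alb albumin concentration, g/L.
#' @return An object of class `"binding_site_params"`.
#' @export
binding_site_params <- function(n, Ka, C_alb) {
  for (f in c("n", "Ka", "C_alb")) {
    v <- get(f)
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("binding_site_params: '%s' must be > 0", f),
           call. = FALSE)
    }
  }
  structure(list(n = n, Ka = Ka, C_alb = C_alb),
            class = "binding_site_params")
}

#' Rescale a fraction unbound to different binding-site parameters
#'
#' Linear (non-saturated), single-site-class binding: the bound:unbound
#' ratio scales with the binding capacity n * Ka * C_alb, so
#' \deqn{fu_{new} = \frac{1}{1 + \frac{1 - fu_{ref}}{fu_{ref}} \cdot
#'   \frac{n_{new} Ka_{new} C_{new}}{n_{ref} Ka_{ref} C_{ref}}}.}
#'
#' @param fu_ref reference fraction unbound, in (0, 1].
#' @param ref,new [binding_site_params()] for the reference and target serum.
#' @return Rescaled fraction unbound.
#' @export
scale_fu_binding_sites <- function(fu_ref, ref, new) {
  stopifnot(inherits(ref, "binding_site_params"),
            inherits(new, "binding_site_params"))
  if (!is.finite(fu_ref) || fu_ref <= 0 || fu_ref > 1) {
    stop("scale_fu_binding_sites: 'fu_ref' must be in (0, 1]", call. = FALSE)
  }
  cap_ratio <- (new$n * new$Ka * new$C_alb) / (ref$n * ref$Ka * ref$C_alb)
  1 / (1 + (1 - fu_ref) / fu_ref * cap_ratio)
}

#' Interstitial : plasma partition coefficient (Schmitt form)
#'
#' \deqn{K_{int,pls} = \left(f_{water,int} + \frac{f_{prot,int}}
#'   {f_{prot,pls}}\left(\frac{1}{fu} - f_{water,pls}\right)\right) fu.}
#' As fu tends to 0 the coefficient tends to the protein-fraction ratio; at
#' fu = 1 it is close to the water-fraction ratio.
#'
#' @param fu fraction unbound of the plasma the coefficient references,
#'   in (0, 1].
#' @param comp a [plasma_composition()].
#' @return The interstitial : plasma partition coefficient (> 0).
#' @export
k_int_pls <- function(fu, comp = plasma_composition()) {
  stopifnot(inherits(comp, "plasma_composition"))
  if (any(!is.finite(fu)) || any(fu <= 0) || any(fu > 1)) {
    stop("k_int_pls: 'fu' must be in (0, 1]", call. = FALSE)
  }
  (comp$f_water_int + comp$fprot_ratio * (1 / fu - comp$f_water_pls)) * fu
}

#' Maternal-fu corrected intracellular concentration coefficient
#'
#' The intracellular partition coefficient used throughout the model is
#' predicted with the maternal fraction unbound as a discrete multiplier.
#' Rather than re-deriving it with fetal binding, the water:cell coefficient
#' is multiplied by the maternal-to-fetal fu ratio, after which the fetal fu
#' cancels: the surviving coefficient on the intracellular concentration is
#' `fu_maternal / K_cell_pls`, independent of `fu_fetal`.
#'
#' @param fu_maternal maternal fraction unbound (> 0).
#' @param K_cell_pls intracellular : plasma partition coefficient (> 0).
#' @return The coefficient `fu_maternal / K_cell_pls`.
#' @export
k_water_cell_corrected <- function(fu_maternal, K_cell_pls) {
  if (any(!is.finite(fu_maternal)) || any(fu_maternal <= 0)) {
    stop("k_water_cell_corrected: 'fu_maternal' must be > 0", call. = FALSE)
  }
  if (any(!is.finite(K_cell_pls)) || any(K_cell_pls <= 0)) {
    stop("k_water_cell_corrected: 'K_cell_pls' must be > 0", call. = FALSE)
  }
  fu_maternal / K_cell_pls
}
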