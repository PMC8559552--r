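# Typed parameter containers and config I/O.
#
# Internal unit convention (applied on load, used everywhere downstream):
# amounts umol, concentrations umol/L, volumes L, time min, clearances L/min,
# permeabilities cm/min, areas cm2. Caco-2 Papp is carried in cm/s as an
# informational field; the basolateral surface area is entered in dm2 (as
# usually quoted for the trophoblast) and converted to cm2 (x100).

#' Dose regimen
#'
#' Describes a dosing schedule for one drug: a single dose or a repeated
#' course at a fixed interval, given as an intravenous bolus, an intravenous
#' infusion of stated duration, or orally.
#'
#' @param dose_mg dose per administration (mg), > 0.
#' @param route one of `"iv_bolus"`, `"iv_infusion"`, `"oral"`.
#' @param n_doses number of administrations (>= 1).
#' @param interval_h dosing interval in hours; required when `n_doses > 1`.
#' @param infusion_duration_min infusion duration in minutes
#'   (`"iv_infusion"` only).
#' @return An object of class `"dose_regimen"`.
#' @export
dose_regimen <- function(dose_mg, route = c("iv_bolus", "iv_infusion", "oral"),
                         n_doses = 1L, interval_h = NA_real_,
                         infusion_duration_min = NA_real_) {
  route <- match.arg(route)
  if (!is.numeric(dose_mg) || length(dose_mg) != 1L || !is.finite(dose_mg) ||
      dose_mg <= 0) {
    stop("dose_regimen: 'dose_mg' must be a single positive number",
         call. = FALSE)
  }
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) {
    stop("dose_regimen: 'n_doses' must be >= 1", call. = FALSE)
  }
  if (n_doses > 1L && (is.na(interval_h) || interval_h <= 0)) {
    stop("dose_regimen: 'interval_h' is required (and must be > 0) when ",
         "'n_doses' > 1", call. = FALSE)
  }
  if (route == "iv_infusion" &&
      (is.na(infusion_duration_min) || infusion_duration_min <= 0)) {
    stop("dose_regimen: 'infusion_duration_min' must be > 0 for an infusion",
         call. = FALSE)
  }
  structure(
    list(dose_mg = dose_mg, route = route, n_doses = n_doses,
         interval_h = as.numeric(interval_h),
         infusion_duration_min = as.numeric(infusion_duration_min)),
    class = "dose_regimen"
  )
}

#' Drug-specific model parameters
#'
#' Container for every drug-specific constant used by the simulator: plasma
#' protein binding in non-pregnant adults, mother and fetus; the placental
#' partition coefficient referencing maternal plasma (`K_apical`) and the
#' fetal-plasma-referenced intracellular partition coefficient
#' (`K_cell_pls_fetal`); the apical transfer clearance (permeability times
#' villous surface area, L/min); the basolateral organ permeability (cm/min);
#' the blood-cell:plasma partition coefficient; molecular weight; and the
#' dose regimen. `K_apical` and `K_cell_pls_fetal` are stored separately even
#' when numerically equal because the apical equilibrium references maternal
#' plasma while the basolateral one references fetal plasma.
#'
#' @param name drug identifier.
#' @param fu_nonpreg,fu_maternal,fu_fetal fractions unbound in (0, 1].
#' @param K_apical maternal plasma : trophoblast intracellular partition
#'   coefficient (> 0).
#' @param K_cell_pls_fetal fetal plasma : intracellular partition coefficient
#'   (> 0).
#' @param CL_apical apical transfer clearance, L/min (>= 0).
#' @param P_basolateral basolateral organ permeability, cm/min (>= 0).
#' @param caco2_papp apparent Caco-2 permeability, cm/s (informational).
#' @param K_bc blood-cell : plasma partition coefficient (> 0).
#' @param molecular_weight g/mol (> 0).
#' @param regimen a [dose_regimen()].
#' @param partition_method label of the tissue-partition prediction method
#'   the partition coefficients come from (informational).
#' @param tlast_h time of the last observed concentration in the clinical
#'   study the drug's evaluation mirrors, hours after the (last) dose; used
#'   as the default AUC window (default 24).
#' @return An object of class `"drug_parameters"`.
#' @export
drug_parameters <- function(name, fu_nonpreg, fu_maternal, fu_fetal,
                            K_apical, K_cell_pls_fetal = K_apical,
                            CL_apical, P_basolateral,
                            caco2_papp = NA_real_, K_bc = 1,
                            molecular_weight, regimen,
                            partition_method = NA_character_,
                            tlast_h = 24) {
  frac <- c(fu_nonpreg = fu_nonpreg, fu_maternal = fu_maternal,
            fu_fetal = fu_fetal)
  for (f in names(frac)) {
    v <- frac[[f]]
    if (!is.finite(v) || v <= 0 || v > 1) {
      stop(sprintf("drug_parameters: '%s' must be in (0, 1], got %s", f,
                   format(v)), call. = FALSE)
    }
  }
  pos <- c(K_apical = K_apical, K_cell_pls_fetal = K_cell_pls_fetal,
           K_bc = K_bc, molecular_weight = molecular_weight)
  for (f in names(pos)) {
    if (!is.finite(pos[[f]]) || pos[[f]] <= 0) {
      stop(sprintf("drug_parameters: '%s' must be > 0", f), call. = FALSE)
    }
  }
  nonneg <- c(CL_apical = CL_apical, P_basolateral = P_basolateral)
  for (f in names(nonneg)) {
    if (!is.finite(nonneg[[f]]) || nonneg[[f]] < 0) {
      stop(sprintf("drug_parameters: '%s' must be >= 0", f), call. = FALSE)
    }
  }
  if (!inherits(regimen, "dose_regimen")) {
    stop("drug_parameters: 'regimen' must be a dose_regimen object",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), fu_nonpreg = fu_nonpreg,
         fu_maternal = fu_maternal, fu_fetal = fu_fetal,
         K_apical = K_apical, K_cell_pls_fetal = K_cell_pls_fetal,
         CL_apical = CL_apical, P_basolateral = P_basolateral,
         caco2_papp = caco2_papp, K_bc = K_bc,
         molecular_weight = molecular_weight, regimen = regimen,
         partition_method = partition_method, tlast_h = tlast_h),
    class = "drug_parameters"
  )
}

#' Placenta physiology and barrier scaling factors
#'
#' @param Q_placenta maternal intervillous blood flow, L/min (default 0.75).
#' @param SA_int_cell_dm2 surface area between trophoblast intracellular and
#'   fetal interstitial space, dm2 (default 56,700); converted to cm2
#'   internally.
#' @param f_in,f_out dimensionless apical influx/efflux scaling factors
#'   (default exactly 1 = symmetric passive transfer).
#' @param g_in,g_out dimensionless basolateral influx/efflux scaling factors
#'   (default exactly 1).
#' @param hct_maternal,hct_fetal hematocrits (fractions).
#' @return An object of class `"placenta_physiology"`.
#' @export
placenta_physiology <- function(Q_placenta = 0.75, SA_int_cell_dm2 = 56700,
                                f_in = 1, f_out = 1, g_in = 1, g_out = 1,
                                hct_maternal = 0.39, hct_fetal = 0.45) {
  vals <- c(Q_placenta = Q_placenta, SA_int_cell_dm2 = SA_int_cell_dm2,
            hct_maternal = hct_maternal, hct_fetal = hct_fetal)
  for (f in names(vals)) {
    if (!is.finite(vals[[f]]) || vals[[f]] <= 0) {
      stop(sprintf("placenta_physiology: '%s' must be > 0", f), call. = FALSE)
    }
  }
  for (h in c(hct_maternal = hct_maternal, hct_fetal = hct_fetal)) {
    if (h >= 1) stop("placenta_physiology: hematocrit must be < 1",
                     call. = FALSE)
  }
  sf <- c(f_in = f_in, f_out = f_out, g_in = g_in, g_out = g_out)
  for (f in names(sf)) {
    if (!is.finite(sf[[f]]) || sf[[f]] < 0) {
      stop(sprintf("placenta_physiology: '%s' must be >= 0", f),
           call. = FALSE)
    }
  }
  structure(
    list(Q_placenta = Q_placenta, SA_int_cell_dm2 = SA_int_cell_dm2,
         SA_int_cell_cm2 = SA_int_cell_dm2 * 100,
         f_in = f_in, f_out = f_out, g_in = g_in, g_out = g_out,
         hct_maternal = hct_maternal, hct_fetal = hct_fetal),
    class = "placenta_physiology"
  )
}

#' Plasma and interstitial composition constants
#'
#' Water and protein volume-fraction constants entering the interstitial :
#' plasma partition coefficient, plus reference albumin concentrations for
#' the fetal fraction-unbound estimate.
#'
#' @param f_water_pls fractional water content of plasma (default 0.926).
#' @param f_water_int fractional water content of interstitial space
#'   (default 0.935).
#' @param fprot_ratio ratio of interstitial to plasma protein volume
#'   fractions (default 0.37).
#' @param Cprot_nonpreg albumin concentration in non-pregnant adult plasma,
#'   g/L (default 46.4).
#' @param Cprot_fetus fetal plasma albumin concentration, g/L (default 38.6,
#'   a 38-week value).
#' @return An object of class `"plasma_composition"`.
#' @export
plasma_composition <- function(f_water_pls = 0.926, f_water_int = 0.935,
                               fprot_ratio = 0.37, Cprot_nonpreg = 46.4,
                               Cprot_fetus = 38.6) {
  for (f in c("f_water_pls", "f_water_int", "fprot_ratio")) {
    v <- get(f)
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop(sprintf("plasma_composition: '%s' must be in (0, 1)", f),
           call. = FALSE)
    }
  }
  for (f in c("Cprot_nonpreg", "Cprot_fetus")) {
    v <- get(f)
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("plasma_composition: '%s' must be > 0", f), call. = FALSE)
    }
  }
  structure(
    list(f_water_pls = f_water_pls, f_water_int = f_water_int,
         fprot_ratio = fprot_ratio, Cprot_nonpreg = Cprot_nonpreg,
         Cprot_fetus = Cprot_fetus),
    class = "plasma_composition"
  )
}

#' Sub-compartment geometry of one fetal organ compartment
#'
#' Volumes of the four sub-compartments (blood cells, plasma, interstitial,
#' intracellular), exchange surface areas, membrane permeabilities, and the
#' blood flow supplying the compartment. `P_int_cell` may be `NA` for the
#' fetal placenta, where it is taken from the drug's basolateral
#' permeability.
#'
#' @param V_bc,V_pls,V_int,V_cell sub-compartment volumes, L.
#' @param SA_bc,SA_end,SA_int_cell surface areas, cm2.
#' @param P_pls_bc,P_end,P_int_cell permeabilities, cm/min.
#' @param Q blood flow, L/min.
#' @return An object of class `"compartment_geometry"`.
#' @export
compartment_geometry <- function(V_bc, V_pls, V_int, V_cell,
                                 SA_bc, SA_end, SA_int_cell,
                                 P_pls_bc, P_end, P_int_cell = NA_real_,
                                 Q) {
  vals <- c(V_bc = V_bc, V_pls = V_pls, V_int = V_int, V_cell = V_cell,
            SA_bc = SA_bc, SA_end = SA_end, SA_int_cell = SA_int_cell,
            P_pls_bc = P_pls_bc, P_end = P_end, Q = Q)
  for (f in names(vals)) {
    if (!is.finite(vals[[f]]) || vals[[f]] < 0) {
      stop(sprintf("compartment_geometry: '%s' must be >= 0 and finite", f),
           call. = FALSE)
    }
  }
  structure(
    list(V_bc = V_bc, V_pls = V_pls, V_int = V_int, V_cell = V_cell,
         SA_bc = SA_bc, SA_end = SA_end, SA_int_cell = SA_int_cell,
         P_pls_bc = P_pls_bc, P_end = P_end, P_int_cell = P_int_cell, Q = Q),
    class = "compartment_geometry"
  )
}

#' Default fetal geometry
#'
#' Default sub-compartment geometry for the lumped fetus, the fetal placenta,
#' the umbilical arterial and venous blood pools, and the (isolated) amniotic
#' fluid pool, for a term (~3.5 kg) fetus. These values are not drug-specific
#' and are editable through the config file; the trophoblast
#' interstitial-intracellular surface area is pinned to 56,700 dm2. The
#' fetal placenta's `P_int_cell` is left `NA` and filled per drug.
#'
#' @param Q_umbilical umbilical blood flow, L/min (default 0.36).
#' @param SA_int_cell_placenta_cm2 trophoblast basolateral surface area, cm2.
#' @return An object of class `"fetal_geometry"`: a list with elements
#'   `fetus` and `placenta` (each a [compartment_geometry()]), umbilical and
#'   amniotic pool volumes, and `Q_umbilical`.
#' @export
fetal_geometry <- function(Q_umbilical = 0.36,
                           SA_int_cell_placenta_cm2 = 56700 * 100) {
  structure(
    list(
      fetus = compartment_geometry(
        V_bc = 0.12, V_pls = 0.15, V_int = 0.90, V_cell = 2.30,
        SA_bc = 1e4, SA_end = 2e4, SA_int_cell = 1e6,
        P_pls_bc = 5e-2, P_end = 5e-2, P_int_cell = 1e-3,
        Q = Q_umbilical),
      placenta = compartment_geometry(
        V_bc = 0.05, V_pls = 0.07, V_int = 0.10, V_cell = 0.25,
        SA_bc = 5e3, SA_end = 1e4, SA_int_cell = SA_int_cell_placenta_cm2,
        P_pls_bc = 5e-2, P_end = 5e-2, P_int_cell = NA_real_,
        Q = Q_umbilical),
      V_umb_art = 0.03, V_umb_ven = 0.05, V_amniotic = 0.8,
      Q_umbilical = Q_umbilical),
    class = "fetal_geometry"
  )
}

#' Load the built-in drug library
#'
#' Reads the library of the eight reference drugs shipped with the package
#' (fractions unbound, placental partition coefficients, apical transfer
#' clearances, basolateral permeabilities, molecular weights and dose
#' regimens). The `P_basolateral_source` column of the underlying CSV marks
#' which basolateral permeabilities are reported values and which are
#' package defaults (see the package vignette).
#'
#' @return A named list of [drug_parameters()] objects.
#' @examples
#' lib <- load_drug_library()
#' lib$metronidazole$CL_apical
#' @export
load_drug_library <- function() {
  path <- system.file("extdata", "drug_library.csv", package = "mfpbpk",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    reg <- dose_regimen(
      dose_mg = r$dose_mg, route = r$route, n_doses = r$n_doses,
      interval_h = r$interval_h,
      infusion_duration_min = r$infusion_duration_min)
    drug_parameters(
      name = r$name, fu_nonpreg = r$fu_nonpreg,
      fu_maternal = r$fu_maternal, fu_fetal = r$fu_fetal,
      K_apical = r$K_cell_pls, K_cell_pls_fetal = r$K_cell_pls,
      CL_apical = r$CL_apical_L_min, P_basolateral = r$P_basolateral_cm_min,
      caco2_papp = r$caco2_papp_cm_s, K_bc = r$K_bc,
      molecular_weight = r$molecular_weight, regimen = reg,
      partition_method = r$partition_method, tlast_h = r$tlast_h)
  })
  names(out) <- tab$name
  out
}

#' Fetch one drug from the built-in library
#'
#' @param name drug name (one of the eight library drugs).
#' @return A [drug_parameters()] object.
#' @export
get_drug <- function(name) {
  lib <- load_drug_library()
  if (!name %in% names(lib)) {
    stop(sprintf("unknown drug '%s'; library drugs: %s", name,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  }
  lib[[name]]
}

# ---- config I/O -----------------------------------------------------------

bundle_fields <- list(
  drug = c("name", "fu_nonpreg", "fu_maternal", "fu_fetal", "K_apical",
           "K_cell_pls_fetal", "CL_apical", "P_basolateral", "caco2_papp",
           "K_bc", "molecular_weight", "partition_method", "tlast_h"),
  regimen = c("dose_mg", "route", "n_doses", "interval_h",
              "infusion_duration_min"),
  placenta = c("Q_placenta", "SA_int_cell_dm2", "f_in", "f_out", "g_in",
               "g_out", "hct_maternal", "hct_fetal"),
  plasma = c("f_water_pls", "f_water_int", "fprot_ratio", "Cprot_nonpreg",
             "Cprot_fetus")
)

#' Load a model configuration file
#'
#' Reads a YAML config with sections `drug`, `regimen`, `placenta`, `plasma`,
#' `geometry` and `maternal`. The `drug` section must at least name a drug;
#' if it is a library drug, unset fields take the library values, otherwise
#' all drug fields are required. All other sections are optional and default
#' to [placenta_physiology()], [plasma_composition()], [fetal_geometry()]
#' and [maternal_defaults()]. Every invariant is checked on load; a value
#' outside its admissible range raises an error naming the field.
#'
#' @param path path to a YAML config file.
#' @return A named list (`drug`, `placenta`, `plasma`, `geometry`,
#'   `maternal`) of validated parameter objects, class `"pbpk_config"`.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drug) || is.null(cfg$drug$name)) {
    stop("config: required field 'drug.name' is missing", call. = FALSE)
  }
  lib <- load_drug_library()
  base <- if (cfg$drug$name %in% names(lib)) lib[[cfg$drug$name]] else NULL

  pick <- function(section, field, default) {
    v <- cfg[[section]][[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v) &&
                       !is.na(default))) default else v
  }

  # drug + regimen
  dfields <- setdiff(bundle_fields$drug, "name")
  dargs <- list(name = cfg$drug$name)
  for (f in dfields) {
    def <- if (!is.null(base)) base[[f]] else NA
    v <- pick("drug", f, def)
    if (is.null(v) || (length(v) == 1L && is.na(v) &&
                       f %in% c("fu_nonpreg", "fu_maternal", "fu_fetal",
                                "K_apical", "CL_apical", "P_basolateral",
                                "molecular_weight"))) {
      stop(sprintf("config: required field 'drug.%s' is missing", f),
           call. = FALSE)
    }
    dargs[[f]] <- v
  }
  rdef <- if (!is.null(base)) base$regimen else NULL
  rargs <- list()
  for (f in bundle_fields$regimen) {
    def <- if (!is.null(rdef)) rdef[[f]] else NA
    rargs[[f]] <- pick("regimen", f, def)
  }
  if (is.null(rargs$dose_mg) || all(is.na(rargs$dose_mg))) {
    stop("config: required field 'regimen.dose_mg' is missing",
         call. = FALSE)
  }
  dargs$regimen <- do.call(dose_regimen, rargs)
  drug <- do.call(drug_parameters, dargs)

  pargs <- list()
  for (f in bundle_fields$placenta) {
    v <- cfg$placenta[[f]]
    if (!is.null(v)) pargs[[f]] <- v
  }
  placenta <- do.call(placenta_physiology, pargs)

  cargs <- list()
  for (f in bundle_fields$plasma) {
    v <- cfg$plasma[[f]]
    if (!is.null(v)) cargs[[f]] <- v
  }
  plasma <- do.call(plasma_composition, cargs)

  geometry <- fetal_geometry(
    Q_umbilical = if (!is.null(cfg$geometry$Q_umbilical))
      cfg$geometry$Q_umbilical else 0.36,
    SA_int_cell_placenta_cm2 = placenta$SA_int_cell_cm2)
  for (comp in c("fetus", "placenta")) {
    sec <- cfg$geometry[[comp]]
    if (!is.null(sec)) {
      g <- geometry[[comp]]
      for (f in names(sec)) {
        if (!f %in% names(g)) {
          stop(sprintf("config: unknown geometry field 'geometry.%s.%s'",
                       comp, f), call. = FALSE)
        }
        g[[f]] <- sec[[f]]
      }
      geometry[[comp]] <- do.call(compartment_geometry, unclass(g))
    }
  }
  for (f in c("V_umb_art", "V_umb_ven", "V_amniotic")) {
    if (!is.null(cfg$geometry[[f]])) geometry[[f]] <- cfg$geometry[[f]]
  }

  maternal <- maternal_defaults(drug$name)
  if (!is.null(cfg$maternal)) {
    for (f in names(cfg$maternal)) {
      if (!f %in% names(maternal)) {
        stop(sprintf("config: unknown maternal field 'maternal.%s'", f),
             call. = FALSE)
      }
      maternal[[f]] <- cfg$maternal[[f]]
    }
    maternal <- do.call(maternal_config, unclass(maternal))
  }

  structure(list(drug = drug, placenta = placenta, plasma = plasma,
                 geometry = geometry, maternal = maternal),
            class = "pbpk_config")
}

#' Write a model configuration file
#'
#' Serialises a validated parameter bundle back to YAML so that
#' `load_config(write_config(bundle, path))` round-trips to an identical
#' bundle.
#'
#' @param bundle a `"pbpk_config"` bundle as returned by [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  stopifnot(inherits(bundle, "pbpk_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
  }
  drug <- strip(bundle$drug)
  reg <- strip(drug$regimen)
  drug$regimen <- NULL
  placenta <- strip(bundle$placenta)
  placenta$SA_int_cell_cm2 <- NULL  # derived on load
  geometry <- list(
    fetus = strip(bundle$geometry$fetus),
    placenta = strip(bundle$geometry$placenta),
    V_umb_art = bundle$geometry$V_umb_art,
    V_umb_ven = bundle$geometry$V_umb_ven,
    V_amniotic = bundle$geometry$V_amniotic,
    Q_umbilical = bundle$geometry$Q_umbilical)
  out <- list(drug = drug, regimen = reg, placenta = placenta,
              plasma = strip(bundle$plasma), geometry = geometry,
              maternal = strip(bundle$maternal))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s\n", x$name))
  cat(sprintf("  fu (non-pregnant / maternal / fetal): %.4g / %.4g / %.4g\n",
              x$fu_nonpreg, x$fu_maternal, x$fu_fetal))
  cat(sprintf("  K_apical %.3g, K_cell_pls_fetal %.3g, K_bc %.3g\n",
              x$K_apical, x$K_cell_pls_fetal, x$K_bc))
  cat(sprintf("  CL_apical %.3g L/min, P_basolateral %.3g cm/min\n",
              x$CL_apical, x$P_basolateral))
  r <- x$regimen
  cat(sprintf("  regimen: %g mg %s x%d%s\n", r$dose_mg, r$route, r$n_doses,
              if (!is.na(r$interval_h)) sprintf(" q%gh", r$interval_h) else ""))
  invisible(x)
}
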