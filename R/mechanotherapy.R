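#' Tissue mechanical parameters
#'
#' Shear modulus, bulk modulus and interstitial hydraulic conductivity of a
#' tissue compartment. Defaults are placeholders in the literature range for
#' murine breast tumors and are exposed in [default_config()].
#'
#' @param shear_modulus_Pa Shear modulus mu, Pa.
#' @param bulk_modulus_Pa Bulk modulus k, Pa.
#' @param hydraulic_conductivity Interstitial hydraulic conductivity k_th,
#'   m^2/(Pa s).
#' @param tissue_class One of `"host"`, `"tumor_untreated"`,
#'   `"tumor_treated"`.
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(shear_modulus_Pa = 1000,
                             bulk_modulus_Pa = 5000,
                             hydraulic_conductivity = 1e-13,
                             tissue_class = c("tumor_untreated", "host",
                                              "tumor_treated")) {
  tissue_class <- match.arg(tissue_class)
  vals <- c(shear_modulus_Pa, bulk_modulus_Pa, hydraulic_conductivity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("moduli and conductivity must be strictly positive", call. = FALSE)
  structure(
    list(shear_modulus_Pa = shear_modulus_Pa,
         bulk_modulus_Pa = bulk_modulus_Pa,
         hydraulic_conductivity = hydraulic_conductivity,
         tissue_class = tissue_class),
    class = "mechanics_params")
}

#' Ketotifen treatment course
#'
#' Daily ketotifen dosing modelled as a direct, linear-in-time modulation of
#' tumor mechanics: over the ramp the shear and bulk moduli fall to half
#' their baselines and the hydraulic conductivity rises 100-fold, after
#' which the factors hold while dosing continues. The dose itself is
#' record-keeping only; the drug is not pharmacokinetically modelled.
#'
#' @param start_time_h Start of daily dosing, hours.
#' @param ramp_duration_h Duration of the linear ramp, hours (default 72,
#'   i.e. the 3 days over which tumor stiffness halves).
#' @param daily_dose_mg_per_kg Recorded daily dose (default 10).
#' @return An object of class `ketotifen_course`.
#' @export
ketotifen_course <- function(start_time_h = 0, ramp_duration_h = 72,
                             daily_dose_mg_per_kg = 10) {
  if (!is.finite(ramp_duration_h) || ramp_duration_h <= 0)
    stop("ramp_duration_h must be positive", call. = FALSE)
  structure(
    list(start_time_h = start_time_h,
         ramp_duration_h = ramp_duration_h,
         daily_dose_mg_per_kg = daily_dose_mg_per_kg),
    class = "ketotifen_course")
}

#' Ketotifen modulation factors at a given time
#'
#' Before the course starts both factors are 1. During the ramp the modulus
#' factor falls linearly from 1 to 0.5 and the conductivity factor rises
#' linearly from 1 to 100; after ramp completion they hold at (0.5, 100) for
#' the remainder of the course (no rebound or washout is modelled, matching
#' continuous daily dosing).
#'
#' @param t Time, hours (scalar or vector, >= 0).
#' @param course A [ketotifen_course()] object, or `NULL` for no treatment.
#' @return A list with numeric elements `modulus_factor` and
#'   `conductivity_factor`, each the length of `t`.
#' @export
ketotifen_modulation <- function(t, course) {
  if (is.null(course))
    return(list(modulus_factor = rep(1, length(t)),
                conductivity_factor = rep(1, length(t))))
  stopifnot(inherits(course, "ketotifen_course"))
  s <- pmin(pmax((t - course$start_time_h) / course$ramp_duration_h, 0), 1)
  list(modulus_factor = 1 - 0.5 * s,
       conductivity_factor = 1 + 99 * s)
}

#' Apply mechanotherapy factors to a tissue parameter bundle
#'
#' Multiplies the tumor's shear and bulk moduli by the modulus factor and its
#' hydraulic conductivity by the conductivity factor. Host tissue is never
#' modified: applying factors to a host bundle is a no-op with a warning.
#'
#' @param params A [mechanics_params()] object.
#' @param factors A list as returned by [ketotifen_modulation()] (scalar
#'   factors).
#' @return A new `mechanics_params` object.
#' @export
apply_mechanotherapy <- function(params, factors) {
  stopifnot(inherits(params, "mechanics_params"))
  if (params$tissue_class == "host") {
    if (factors$modulus_factor != 1 || factors$conductivity_factor != 1)
      warning("mechanotherapy factors ignored for host tissue", call. = FALSE)
    return(params)
  }
  out <- params
  out$shear_modulus_Pa <- params$shear_modulus_Pa * factors$modulus_factor
  out$bulk_modulus_Pa <- params$bulk_modulus_Pa * factors$modulus_factor
  out$hydraulic_conductivity <-
    params$hydraulic_conductivity * factors$conductivity_factor
  if (factors$modulus_factor < 1 || factors$conductivity_factor > 1)
    out$tissue_class <- "tumor_treated"
  out
}
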