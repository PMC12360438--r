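#' Sonopermeation pulse
#'
#' One ultrasound + microbubble application. The transmitted wave is
#' characterised by its mechanical index (MI) and centre frequency; the
#' biological effect (dilated vessel-wall pores, microstreaming wall shear
#' stress on the endothelium) acts over a finite window after the pulse,
#' by default 6 hours.
#'
#' @param mechanical_index Dimensionless MI (peak negative pressure in MPa
#'   divided by the square root of the frequency in MHz). Must be >= 0.
#' @param frequency_MHz Transducer centre frequency in MHz. Must be > 0.
#' @param start_time_h Application time in hours from simulation start.
#' @param effect_duration_h Duration of the permeability/shear effect window
#'   in hours (default 6).
#' @param microbubble A [microbubble_params()] object.
#' @return An object of class `sono_pulse`.
#' @seealso [acoustic_pressure()], [sono_effect()]
#' @export
sono_pulse <- function(mechanical_index = 0.4, frequency_MHz = 1,
                       start_time_h = 0, effect_duration_h = 6,
                       microbubble = microbubble_params()) {
  if (!is.finite(mechanical_index) || mechanical_index < 0)
    stop("mechanical_index must be a non-negative number", call. = FALSE)
  if (!is.finite(frequency_MHz) || frequency_MHz <= 0)
    stop("frequency_MHz must be positive", call. = FALSE)
  if (!is.finite(effect_duration_h) || effect_duration_h <= 0)
    stop("effect_duration_h must be positive", call. = FALSE)
  stopifnot(inherits(microbubble, "microbubble_params"))
  structure(
    list(mechanical_index = mechanical_index,
         frequency_MHz = frequency_MHz,
         start_time_h = start_time_h,
         effect_duration_h = effect_duration_h,
         microbubble = microbubble),
    class = "sono_pulse")
}

#' Microbubble parameters
#'
#' Physical parameters of the shelled microbubble and its surrounding liquid
#' (blood) entering the microstreaming wall shear stress expression.
#'
#' @param liquid_density Density of the surrounding liquid, kg/m^3.
#' @param liquid_viscosity Viscosity of the surrounding liquid, Pa s.
#' @param wall_displacement_amplitude Oscillation amplitude of the bubble
#'   wall, m.
#' @param equilibrium_radius Equilibrium radius of the shelled bubble, m.
#' @return An object of class `microbubble_params`.
#' @export
microbubble_params <- function(liquid_density = 1060,
                               liquid_viscosity = 4e-3,
                               wall_displacement_amplitude = 5e-8,
                               equilibrium_radius = 1.7e-6) {
  vals <- c(liquid_density, liquid_viscosity,
            wall_displacement_amplitude, equilibrium_radius)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all microbubble parameters must be strictly positive", call. = FALSE)
  structure(
    list(liquid_density = liquid_density,
         liquid_viscosity = liquid_viscosity,
         wall_displacement_amplitude = wall_displacement_amplitude,
         equilibrium_radius = equilibrium_radius),
    class = "microbubble_params")
}

#' Vessel-wall pore dilation law
#'
#' Quadratic law mapping acoustic pressure (MPa) to vessel-wall pore radius
#' (nm), fitted to experimental pore-size measurements. The raw polynomial is
#' negative at zero pressure and beyond ~0.55 MPa, so evaluated pore radii are
#' clamped to `[baseline_pore_radius, max_pore_radius]`.
#'
#' @param quad_coeff Quadratic coefficient, nm/MPa^2.
#' @param lin_coeff Linear coefficient, nm/MPa.
#' @param const_coeff Constant term, nm.
#' @param baseline_pore_radius Pore radius of the unsonicated vessel wall, nm.
#'   The default (200 nm) reflects the leaky cut-off of tumor microvessels,
#'   through which nanocarriers extravasate even without ultrasound.
#' @param max_pore_radius Upper clamp, nm; default 1250 nm, the upper end of
#'   the experimentally reported dilated-pore range.
#' @return An object of class `pore_law`.
#' @export
pore_law <- function(quad_coeff = -14977.9087, lin_coeff = 8208.3947,
                     const_coeff = -69.0722,
                     baseline_pore_radius = 200, max_pore_radius = 1250) {
  if (!is.finite(baseline_pore_radius) || baseline_pore_radius <= 0)
    stop("baseline_pore_radius must be positive", call. = FALSE)
  if (max_pore_radius < baseline_pore_radius)
    stop("max_pore_radius must be >= baseline_pore_radius", call. = FALSE)
  structure(
    list(quad_coeff = quad_coeff, lin_coeff = lin_coeff,
         const_coeff = const_coeff,
         baseline_pore_radius = baseline_pore_radius,
         max_pore_radius = max_pore_radius),
    class = "pore_law")
}

#' Acoustic pressure of a sonopermeation pulse
#'
#' p_ac = MI * sqrt(fr), in MPa when the frequency is in MHz (this is the
#' defining convention of the mechanical index).
#'
#' @param pulse A [sono_pulse()] object.
#' @return Acoustic pressure in MPa.
#' @export
acoustic_pressure <- function(pulse) {
  stopifnot(inherits(pulse, "sono_pulse"))
  pulse$mechanical_index * sqrt(pulse$frequency_MHz)
}

#' Pore radius at a given acoustic pressure
#'
#' Evaluates the quadratic pore-dilation law and clamps the result to the
#' admissible range. With `clamp = FALSE` the raw polynomial is returned
#' (negative values included), which is what the fitted law itself predicts
#' outside its calibrated range.
#'
#' @param p_ac Acoustic pressure, MPa (scalar or vector, >= 0).
#' @param law A [pore_law()] object.
#' @param clamp Clamp the result to
#'   `[baseline_pore_radius, max_pore_radius]`? Default `TRUE`.
#' @return Pore radius in nm, same length as `p_ac`.
#' @export
pore_radius <- function(p_ac, law = pore_law(), clamp = TRUE) {
  stopifnot(inherits(law, "pore_law"))
  if (any(!is.finite(p_ac)) || any(p_ac < 0))
    stop("p_ac must be non-negative", call. = FALSE)
  raw <- law$quad_coeff * p_ac^2 + law$lin_coeff * p_ac + law$const_coeff
  if (!clamp) return(raw)
  pmin(pmax(raw, law$baseline_pore_radius), law$max_pore_radius)
}

#' Microstreaming wall shear stress
#'
#' Steady shear stress exerted on the endothelium by the oscillation of a
#' shelled microbubble near the vessel wall:
#' tau = sqrt(2 rho_L mu_L) (2 pi fr)^(3/2) eta_m^2 / R_0,
#' with the frequency converted to Hz. The constant prefactor of this
#' Nyborg-type microstreaming stress is configurable; all scaling behaviour
#' (tau ~ eta_m^2, fr^(3/2), 1/R_0, sqrt(rho_L mu_L)) is
#' prefactor-independent.
#'
#' @param pulse A [sono_pulse()] object.
#' @param prefactor Dimensionless constant multiplying the expression
#'   (default 1).
#' @return Wall shear stress in Pa.
#' @export
wall_shear_stress <- function(pulse, prefactor = 1) {
  stopifnot(inherits(pulse, "sono_pulse"))
  mb <- pulse$microbubble
  fr_hz <- pulse$frequency_MHz * 1e6
  prefactor * sqrt(2 * mb$liquid_density * mb$liquid_viscosity) *
    (2 * pi * fr_hz)^1.5 *
    mb$wall_displacement_amplitude^2 / mb$equilibrium_radius
}

#' Endothelial proliferation modulation by wall shear stress
#'
#' Fitted quadratic pr(tau) = -3e-6 tau^2 + 0.0067 tau + 0.2533, floored at
#' zero (the fitted parabola turns negative at large stress, and a negative
#' proliferation multiplier is unphysical). Multiplies the endothelial-cell
#' proliferation term.
#'
#' @param tau Wall shear stress, Pa (scalar or vector, >= 0).
#' @return Dimensionless multiplication factor.
#' @export
proliferation_factor <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("tau must be non-negative", call. = FALSE)
  pmax(-3e-6 * tau^2 + 0.0067 * tau + 0.2533, 0)
}

#' Endothelial apoptosis modulation by wall shear stress
#'
#' Fitted quadratic ap(tau) = -3e-5 tau^2 + 0.0126 tau + 0.6666, floored at
#' zero. Multiplies the endothelial-cell apoptosis term.
#'
#' @inheritParams proliferation_factor
#' @return Dimensionless multiplication factor.
#' @export
apoptosis_factor <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("tau must be non-negative", call. = FALSE)
  pmax(-3e-5 * tau^2 + 0.0126 * tau + 0.6666, 0)
}

#' Active sonopermeation effect at a given time
#'
#' Combines a list of pulses into the instantaneous vessel-wall state.
#' During the effect window of a pulse the pore radius is dilated per the
#' pore law and the endothelium experiences the microstreaming shear stress;
#' outside all windows the wall is at baseline and the stress is zero.
#' Overlapping pulses are resolved by taking the maximum effect. The default
#' envelope is rectangular (full strength for the whole window); the
#' `"linear"` variant decays linearly from full strength at window entry to
#' zero at window close.
#'
#' @param t Time, hours.
#' @param pulses List of [sono_pulse()] objects (may be empty).
#' @param law A [pore_law()] object.
#' @param envelope `"rectangular"` (default) or `"linear"`.
#' @param prefactor Shear-stress prefactor, see [wall_shear_stress()].
#' @return A list with elements `pore_radius_nm` and `tau_Pa`.
#' @export
sono_effect <- function(t, pulses, law = pore_law(),
                        envelope = c("rectangular", "linear"),
                        prefactor = 1) {
  envelope <- match.arg(envelope)
  best_pore <- law$baseline_pore_radius
  best_tau <- 0
  for (p in pulses) {
    el <- t - p$start_time_h
    if (el < 0 || el > p$effect_duration_h) next
    w <- if (envelope == "rectangular") 1 else 1 - el / p$effect_duration_h
    r_full <- pore_radius(acoustic_pressure(p), law)
    r_t <- law$baseline_pore_radius + w * (r_full - law$baseline_pore_radius)
    tau_t <- w * wall_shear_stress(p, prefactor)
    best_pore <- max(best_pore, r_t)
    best_tau <- max(best_tau, tau_t)
  }
  list(pore_radius_nm = best_pore, tau_Pa = best_tau)
}
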