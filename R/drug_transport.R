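#' Drug species parameter bundle
#'
#' Transport and kinetic parameters for one administered agent. The
#' nanocarrier (Doxil) carries release/internalization kinetics; the
#' checkpoint antibody (anti-PD-1) is a free agent with degradation only.
#' All tissue and plasma concentrations are dimensionless, normalized to the
#' plasma peak of a single bolus (1 at injection); `dose_mg_per_kg` is
#' metadata.
#'
#' @param name Label, e.g. `"doxil"` or `"anti_pd1"`.
#' @param molecular_radius_nm Hydrodynamic radius of the circulating species,
#'   nm.
#' @param D_m2_per_s Interstitial diffusivity of the species, m^2/s.
#' @param D_free_m2_per_s Interstitial diffusivity of the released free drug
#'   (nanocarrier only), m^2/s.
#' @param k_el_per_s Payload release rate from the carrier, 1/s
#'   (nanocarrier only).
#' @param k_int_per_s Cellular internalization rate of free drug, 1/s.
#' @param k_deg_per_s Degradation rate (internalized drug for the carrier
#'   species, free antibody for checkpoint inhibitors), 1/s.
#' @param alpha Payload molecules per carrier, in normalized concentration
#'   units (>= 1 for nanocarriers; 1 means free-drug amounts are measured in
#'   carrier-payload equivalents).
#' @param k_d_h Plasma bolus decay time constant, hours.
#' @param dose_mg_per_kg Recorded dose.
#' @param injection_times_h Numeric vector of injection times, hours.
#' @return An object of class `drug_species`.
#' @export
drug_species <- function(name, molecular_radius_nm, D_m2_per_s,
                         D_free_m2_per_s = NA, k_el_per_s = 0,
                         k_int_per_s = 0, k_deg_per_s = 0, alpha = 1,
                         k_d_h = 24, dose_mg_per_kg = NA,
                         injection_times_h = numeric()) {
  if (molecular_radius_nm <= 0) stop("molecular_radius_nm must be > 0",
                                     call. = FALSE)
  rates <- c(k_el_per_s, k_int_per_s, k_deg_per_s)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  structure(
    list(name = name, molecular_radius_nm = molecular_radius_nm,
         D_m2_per_s = D_m2_per_s, D_free_m2_per_s = D_free_m2_per_s,
         k_el_per_s = k_el_per_s, k_int_per_s = k_int_per_s,
         k_deg_per_s = k_deg_per_s, alpha = alpha, k_d_h = k_d_h,
         dose_mg_per_kg = dose_mg_per_kg,
         injection_times_h = sort(injection_times_h)),
    class = "drug_species")
}

#' Vessel-wall transport coefficients
#'
#' Pore radius, wall filtration conductivity, vascular pressure and
#' per-species permeability/reflection. `Per` and `sigma_f` should be named
#' numeric vectors (one entry per species).
#'
#' @param pore_radius_nm Wall pore radius, nm.
#' @param Lp_m_per_Pa_s Wall hydraulic conductivity L_p, m/(Pa s).
#' @param P_V_Pa Microvascular pressure, Pa.
#' @param Per_m_per_s Named vector of diffusive wall permeabilities, m/s.
#' @param sigma_f Named vector of reflection coefficients in `[0, 1]`.
#' @return An object of class `vessel_wall`.
#' @export
vessel_wall <- function(pore_radius_nm = 200, Lp_m_per_Pa_s = 2.1e-11,
                        P_V_Pa = 2000, Per_m_per_s = c(doxil = 1e-8),
                        sigma_f = c(doxil = 0.2)) {
  if (any(sigma_f < 0 | sigma_f > 1))
    stop("sigma_f must lie in [0, 1]", call. = FALSE)
  if (any(Per_m_per_s < 0) || Lp_m_per_Pa_s < 0)
    stop("Per and Lp must be >= 0", call. = FALSE)
  structure(
    list(pore_radius_nm = pore_radius_nm, Lp_m_per_Pa_s = Lp_m_per_Pa_s,
         P_V_Pa = P_V_Pa, Per_m_per_s = Per_m_per_s, sigma_f = sigma_f),
    class = "vessel_wall")
}

#' Plasma concentration after bolus injection(s)
#'
#' Mono-exponential bolus decay C_iv = exp(-(t - t0)/k_d) for t >= t0, zero
#' before injection. Multiple injections superpose; the sum is capped at
#' `ceiling` (re-dosing tops the plasma pool up to its peak).
#'
#' @param t Time, hours (scalar or vector).
#' @param t_0 Injection times, hours (vector).
#' @param k_d Plasma decay time constant, hours (> 0).
#' @param ceiling Cap on the superposed concentration (default 1).
#' @return Dimensionless plasma concentration, same length as `t`.
#' @export
plasma_concentration <- function(t, t_0, k_d, ceiling = 1) {
  if (k_d <= 0) stop("k_d must be positive", call. = FALSE)
  out <- numeric(length(t))
  for (t0 in t_0) {
    dt <- t - t0
    out <- out + ifelse(dt >= 0, exp(-dt / k_d), 0)
  }
  pmin(out, ceiling)
}

#' Hindered pore-transport coefficients
#'
#' Standard cylindrical-pore hindered transport closure for a spherical
#' solute of radius r_s in a pore of radius r_o, as a function of
#' lambda = r_s/r_o: steric partition Phi = (1 - lambda)^2, centreline
#' diffusive hindrance
#' H = Phi (1 - 2.104 lambda + 2.089 lambda^3 - 0.948 lambda^5),
#' and reflection coefficient
#' sigma_f = 1 - (1 - (1 - Phi)^2) G(lambda) with the convective hindrance
#' G(lambda) = 1 - (2/3) lambda^2 - 0.163 lambda^3.
#' All outputs lie in `[0, 1]`; H -> 0 and sigma_f -> 1 as lambda -> 1.
#'
#' @param lambda Solute-to-pore radius ratio in `[0, 1]` (scalar or vector).
#' @return A list with numeric elements `H`, `sigma_f`, `Phi`.
#' @export
hindrance_coefficients <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0 | lambda > 1))
    stop("lambda must lie in [0, 1]", call. = FALSE)
  Phi <- (1 - lambda)^2
  H <- Phi * (1 - 2.104 * lambda + 2.089 * lambda^3 - 0.948 * lambda^5)
  G <- 1 - (2 / 3) * lambda^2 - 0.163 * lambda^3
  sigma_f <- 1 - (1 - (1 - Phi)^2) * G
  list(H = pmin(pmax(H, 0), 1), sigma_f = pmin(pmax(sigma_f, 0), 1),
       Phi = Phi)
}

#' Wall coefficients at a dilated pore radius
#'
#' Rescales the baseline vessel-wall coefficients to a new pore radius:
#' L_p scales as r_o^2 (Poiseuille pore flow at fixed pore areal fraction
#' and wall thickness); the diffusive permeability scales as
#' H(lambda) r_o^2 relative to its baseline anchor (hindrance relief plus
#' the grown open-pore area of dilated pores); the reflection coefficient
#' is re-evaluated from the hindrance closure at the new lambda. Enlarging
#' the pore never decreases P_er or L_p and never increases sigma_f.
#'
#' @param r_o New pore radius, nm. Values below the baseline are clamped to
#'   it with a warning.
#' @param species A [drug_species()] object.
#' @param base A [vessel_wall()] at the baseline pore radius; must carry a
#'   `Per_m_per_s` entry named after the species.
#' @return A new `vessel_wall` with updated `pore_radius_nm`,
#'   `Lp_m_per_Pa_s`, and the species' `Per_m_per_s` and `sigma_f`.
#' @export
wall_coefficients <- function(r_o, species, base) {
  stopifnot(inherits(species, "drug_species"), inherits(base, "vessel_wall"))
  r_b <- base$pore_radius_nm
  if (r_o < r_b) {
    warning("pore radius below baseline; clamped", call. = FALSE)
    r_o <- r_b
  }
  lam_b <- min(species$molecular_radius_nm / r_b, 1)
  lam <- min(species$molecular_radius_nm / r_o, 1)
  hb <- hindrance_coefficients(lam_b)
  h <- hindrance_coefficients(lam)
  if (hb$H <= 0)
    stop("species is fully excluded at the baseline pore radius; no anchor",
         call. = FALSE)
  out <- base
  out$pore_radius_nm <- r_o
  out$Lp_m_per_Pa_s <- base$Lp_m_per_Pa_s * (r_o / r_b)^2
  per <- base$Per_m_per_s
  per[species$name] <- per[species$name] * (h$H / hb$H) * (r_o / r_b)^2
  sig <- base$sigma_f
  sig[species$name] <- h$sigma_f
  out$Per_m_per_s <- per
  out$sigma_f <- sig
  out
}

#' Starling transvascular flux
#'
#' Q_sta = P_er Sv (C_iv - c) + L_p Sv (P_V - p_i) (1 - sigma_f) C_iv:
#' a diffusive exchange term plus convective filtration driven by the
#' transvascular pressure difference, carried at the plasma concentration
#' and hindered by the reflection coefficient.
#'
#' @param Per Wall permeability, m/s (here used in 1/h-compatible units by
#'   the caller; the formula is unit-agnostic).
#' @param Sv Functional vascular surface area per volume, 1/m (scalar or
#'   vector).
#' @param C_iv Plasma concentration (dimensionless).
#' @param c_n Local tissue concentration of the circulating species.
#' @param Lp Wall filtration conductivity.
#' @param P_V Vascular pressure, Pa.
#' @param p_i Interstitial fluid pressure, Pa (scalar or vector).
#' @param sigma_f Reflection coefficient.
#' @return Volumetric source, concentration per unit time.
#' @export
starling_flux <- function(Per, Sv, C_iv, c_n, Lp, P_V, p_i, sigma_f) {
  if (any(Sv < 0)) stop("Sv must be >= 0", call. = FALSE)
  Per * Sv * (C_iv - c_n) + Lp * Sv * (P_V - p_i) * (1 - sigma_f) * C_iv
}

#' Time derivatives of the drug fields
#'
#' Right-hand side of the three-state nanomedicine transport system plus the
#' checkpoint-antibody equation, in spherical radial form with symmetry at
#' r = 0:
#' \itemize{
#'   \item carrier: dc_n/dt = -div(c_n v_f) + D_n lap c_n + Q_sta - k_el c_n
#'   \item free drug: dc_f/dt = -div(c_f v_f) + D_f lap c_f
#'     + alpha k_el c_n - k_int c_f
#'   \item internalized: dc_int/dt = -div(c_int v_s) + k_int c_f
#'     - k_deg c_int
#'   \item antibody: dc_f_i/dt = -div(c_f_i v_f) + D_f_i lap c_f_i
#'     + Q_sta_i - k_deg_i c_f_i
#' }
#' Advection is first-order upwind; diffusion is conservative finite-volume.
#' Rates are converted from 1/s to 1/h internally (time is in hours).
#'
#' @param fields List with numeric vectors `cn`, `cf`, `cint`, `cfi` on the
#'   grid (all >= 0).
#' @param grid A [radial_grid()].
#' @param wall A [vessel_wall()] with `Per_m_per_s`/`sigma_f` entries named
#'   `"doxil"` and `"anti_pd1"`.
#' @param species List with [drug_species()] elements `doxil` and
#'   `anti_pd1`.
#' @param vel List with face-velocity vectors `v_f`, `v_s` (length n+1,
#'   m/h) and cell-centre grid-motion speeds `w` (length n, m/h; zero for a
#'   static domain).
#' @param plasma List with scalars `C_iv` (carrier) and `C_iv_i` (antibody)
#'   at the current time.
#' @param Sv Functional vascular density on the grid, 1/m.
#' @param p_i Interstitial fluid pressure on the grid, Pa.
#' @param bc Outer boundary condition for diffusing species:
#'   `"dirichlet"` (host sink, concentration 0 at r = R; default) or
#'   `"zero_flux"` (closed system).
#' @return A list with `dcn`, `dcf`, `dcint`, `dcfi` (per hour) and
#'   `deg_rate` — the instantaneous total degradation rate
#'   k_deg * integral(c_int) + k_deg_i * integral(c_f_i), used as a
#'   quadrature state for mass-balance accounting.
#' @export
transport_rhs <- function(fields, grid, wall, species, vel, plasma, Sv, p_i,
                          bc = c("dirichlet", "zero_flux")) {
  bc <- match.arg(bc)
  dox <- species$doxil
  pd1 <- species$anti_pd1
  s <- 3600                                   # 1/s -> 1/h
  D_n <- dox$D_m2_per_s * s
  D_f <- dox$D_free_m2_per_s * s
  D_i <- pd1$D_m2_per_s * s
  k_el <- dox$k_el_per_s * s
  k_int <- dox$k_int_per_s * s
  k_deg <- dox$k_deg_per_s * s
  k_deg_i <- pd1$k_deg_per_s * s

  q_n <- starling_flux(wall$Per_m_per_s[["doxil"]] * s, Sv, plasma$C_iv,
                       fields$cn, wall$Lp_m_per_Pa_s * s, wall$P_V_Pa, p_i,
                       wall$sigma_f[["doxil"]])
  q_i <- starling_flux(wall$Per_m_per_s[["anti_pd1"]] * s, Sv, plasma$C_iv_i,
                       fields$cfi, wall$Lp_m_per_Pa_s * s, wall$P_V_Pa, p_i,
                       wall$sigma_f[["anti_pd1"]])

  dcn <- advection_op(fields$cn, vel$v_f, grid) +
    grid_motion_op(fields$cn, vel$w, grid) +
    diffusion_op(fields$cn, D_n, grid, bc) + q_n - k_el * fields$cn
  dcf <- advection_op(fields$cf, vel$v_f, grid) +
    grid_motion_op(fields$cf, vel$w, grid) +
    diffusion_op(fields$cf, D_f, grid, bc) +
    dox$alpha * k_el * fields$cn - k_int * fields$cf
  dcint <- advection_op(fields$cint, vel$v_s, grid) +
    grid_motion_op(fields$cint, vel$w, grid) +
    k_int * fields$cf - k_deg * fields$cint
  dcfi <- advection_op(fields$cfi, vel$v_f, grid) +
    grid_motion_op(fields$cfi, vel$w, grid) +
    diffusion_op(fields$cfi, D_i, grid, bc) + q_i - k_deg_i * fields$cfi

  list(dcn = dcn, dcf = dcf, dcint = dcint, dcfi = dcfi,
       deg_rate = k_deg * volume_integral(fields$cint, grid) +
         k_deg_i * volume_integral(fields$cfi, grid))
}

#' Checkpoint-inhibitor pharmacodynamics
#'
#' Anti-PD-1 raises the CD8+ T-cell source term with a saturating (Hill,
#' coefficient 1) response to the local free-antibody concentration:
#' sigma_T8_eff = sigma_T8 (1 + a_pd1 c/(c_half + c)). Anti-CTLA-4 is not
#' spatially transported; during its effect window after each dose it
#' elevates the regulatory T-cell mortality:
#' m_reg_eff = m_reg (1 + a_ctla4).
#'
#' @param c_f_i Local anti-PD-1 concentration (scalar or vector, >= 0).
#' @param sigma_T8 Baseline CD8+ source term.
#' @param m_reg Baseline Treg mortality rate.
#' @param params List with `a_pd1`, `c_half`, `a_ctla4` (see
#'   [default_config()]`$ici`).
#' @param ctla4_active Logical: is an anti-CTLA-4 dose window open?
#' @return A list with `sigma_T8_eff` (same length as `c_f_i`) and
#'   `m_reg_eff` (scalar).
#' @export
ici_pharmacodynamics <- function(c_f_i, sigma_T8, m_reg, params,
                                 ctla4_active = FALSE) {
  if (any(c_f_i < 0)) stop("c_f_i must be >= 0", call. = FALSE)
  list(
    sigma_T8_eff = sigma_T8 *
      (1 + params$a_pd1 * c_f_i / (params$c_half + c_f_i)),
    m_reg_eff = m_reg * (1 + if (ctla4_active) params$a_ctla4 else 0))
}
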