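#' Growth-induced solid stress
#'
#' Scalar bulk solid stress generated by accumulated volumetric growth,
#' linear in the effective confined modulus:
#' sigma_s = gamma_sigma (k + 4/3 mu) ln(J), floored at zero, where J is
#' the local growth stretch (relative volume gain of the tissue element) and
#' gamma_sigma a dimensionless coupling. Halving both moduli at fixed growth
#' history halves the stress — the lever through which ketotifen
#' decompresses vessels.
#'
#' @param growth_stretch Growth stretch J >= 1 (vector); J = 1 means no net
#'   growth.
#' @param mechanics A [mechanics_params()] object (tumor values, after any
#'   mechanotherapy factors).
#' @param gamma_sigma Dimensionless stress coupling (default 0.3).
#' @return Solid stress vector, Pa.
#' @export
solid_stress <- function(growth_stretch, mechanics, gamma_sigma = 0.3) {
  stopifnot(inherits(mechanics, "mechanics_params"))
  E_eff <- mechanics$bulk_modulus_Pa + 4 / 3 * mechanics$shear_modulus_Pa
  pmax(gamma_sigma * E_eff * log(pmax(growth_stretch, 1e-12)), 0)
}

#' Functional vascular density under compression
#'
#' Sv = Sv_anatomic(endo) exp(-beta_c sigma_s / sigma_ref): solid stress
#' compresses intratumoral vessels and removes them from the perfused pool;
#' at zero stress the functional density equals the anatomic density, which
#' is proportional to the endothelial cell density.
#'
#' @param endo Endothelial density vector (normalized).
#' @param sigma_s Solid stress vector, Pa (>= 0).
#' @param vasc Vasculature parameter list with `Sv_ref_per_m`, `endo_ref`,
#'   `beta_c`, `sigma_ref_Pa` (see [default_config()]`$vasculature`).
#' @return A list with vectors `Sv` (functional, 1/m) and `Sv_anatomic`.
#' @export
functional_vascular_density <- function(endo, sigma_s, vasc) {
  if (any(endo < 0) || any(sigma_s < 0))
    stop("endo and sigma_s must be >= 0", call. = FALSE)
  Sv_an <- vasc$Sv_ref_per_m * endo / vasc$endo_ref
  list(Sv = Sv_an * exp(-vasc$beta_c * sigma_s / vasc$sigma_ref_Pa),
       Sv_anatomic = Sv_an)
}

#' Closed-form interstitial fluid pressure (uniform parameters)
#'
#' Analytic steady solution of the filtration balance on a uniformly
#' vascularized sphere with a zero-pressure datum at the boundary:
#' p_i(r) = P_V (1 - (R/r) sinh(alpha r/R)/sinh(alpha)),
#' alpha = R sqrt(L_p Sv / k_th). At the centre
#' p_i(0) = P_V (1 - alpha/sinh(alpha)).
#'
#' @param r Radii at which to evaluate, m (0 allowed).
#' @param R Tumor radius, m.
#' @param alpha Dimensionless filtration-to-conduction ratio.
#' @param P_V Vascular pressure, Pa.
#' @return Pressure vector, Pa.
#' @export
ifp_closed_form <- function(r, R, alpha, P_V) {
  x <- r / R
  ratio <- ifelse(x == 0, alpha, sinh(alpha * x) / x)
  P_V * (1 - ratio / sinh(alpha))
}

#' Interstitial fluid pressure (elliptic solve)
#'
#' Solves the quasi-static poroelastic filtration balance
#' -div(k_th grad p_i) = L_p Sv (P_V - p_i) on the sphere, with symmetry at
#' r = 0 and p_i = 0 at r = R (well-drained host datum). Spatially variable
#' `Sv`, `Lp` and `k_th` are supported; for uniform parameters the solution
#' matches [ifp_closed_form()].
#'
#' @param Sv Functional vascular density vector on the grid, 1/m.
#' @param Lp Wall filtration conductivity, m/(Pa s) (scalar or vector).
#' @param P_V Vascular pressure, Pa.
#' @param k_th Tissue hydraulic conductivity, m^2/(Pa s) (scalar or vector
#'   at cell centres).
#' @param grid A [radial_grid()].
#' @return A list with `p_i` (cell-centre pressures, Pa) and `dpdr_face`
#'   (pressure gradient at the n+1 faces, Pa/m).
#' @export
interstitial_fluid_pressure <- function(Sv, Lp, P_V, k_th, grid) {
  n <- grid$n
  k_th <- rep_len(k_th, n)
  src <- rep_len(Lp, n) * Sv                  # 1/(Pa s) units absorbed
  # harmonic-mean face conductivities
  k_face <- 2 * k_th[-n] * k_th[-1] / (k_th[-n] + k_th[-1])
  wlo <- c(0, grid$area[2:n] * k_face / grid$dr)          # coupling to i-1
  whi <- c(grid$area[2:n] * k_face / grid$dr,
           grid$area[n + 1] * k_th[n] / (grid$dr / 2))    # i+1 / boundary
  diag_main <- (wlo + whi) / grid$vol + src
  off <- -wlo[-1] / grid$vol[-1]              # sub-diagonal entries
  offu <- -whi[-n] / grid$vol[-n]             # super-diagonal entries
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(off, diag_main, offu))
  rhs <- src * P_V                            # boundary p = 0 contributes 0
  p <- as.numeric(Matrix::solve(A, rhs))
  dpdr <- c(0, diff(p) / grid$dr, (0 - p[n]) / (grid$dr / 2))
  list(p_i = p, dpdr_face = dpdr)
}

#' Fluid and solid phase velocities
#'
#' Darcy fluid velocity v_f = -k_th dp_i/dr at the shell faces, and solid
#' (growth) velocity from the mass balance of the solid phase,
#' v_s(r) = (1/r^2) integral_0^r g r'^2 dr', where g is the net volumetric
#' production rate. Both vanish at r = 0 by symmetry; v_s(R) is the
#' boundary growth speed dR/dt.
#'
#' @param dpdr_face Pressure gradient at faces, Pa/m (length n+1), from
#'   [interstitial_fluid_pressure()].
#' @param k_th Tissue hydraulic conductivity, m^2/(Pa s).
#' @param g Net volumetric growth rate at cell centres, 1/h.
#' @param grid A [radial_grid()].
#' @return A list with face-velocity vectors `v_f` and `v_s` (m/h) and the
#'   boundary speed `dRdt` (m/h).
#' @export
velocities <- function(dpdr_face, k_th, g, grid) {
  n <- grid$n
  v_f <- -rep_len(k_th, n + 1) * 3600 * dpdr_face    # m/h
  shell <- (grid$r_face[-1]^3 - grid$r_face[-(n + 1)]^3) / 3
  cum <- c(0, cumsum(g * shell))
  v_s <- c(0, cum[-1] / grid$r_face[-1]^2)
  list(v_f = v_f, v_s = v_s, dRdt = v_s[n + 1])
}

#' Perfusion surrogate
#'
#' Volume-averaged functional vascular density over the tumor — the model's
#' counterpart of the experimentally measured perfused area. Reported raw
#' and, in arm comparisons, as fold change versus the control run.
#'
#' @param Sv Functional vascular density vector, 1/m.
#' @param grid A [radial_grid()].
#' @return Scalar mean Sv, 1/m.
#' @export
perfusion_metric <- function(Sv, grid) volume_average(Sv, grid)
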