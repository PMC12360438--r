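#' Radial finite-volume grid on a sphere
#'
#' Cell-centred grid on the tumor radius `[0, R]` used by all spatial
#' operators. Cells are equal-width shells; `r` are the cell centres,
#' `r_face` the N+1 shell faces, `area` the face areas and `vol` the shell
#' volumes, so that discrete conservation holds exactly under the face-flux
#' operators below.
#'
#' @param R Domain (tumor) radius in metres.
#' @param n Number of radial cells.
#' @return An object of class `radial_grid` with elements `n`, `R`, `dr`,
#'   `r`, `r_face`, `area` (face areas, length n+1), `vol` (cell volumes,
#'   length n), `xi` (normalized cell centres r/R).
#' @export
radial_grid <- function(R, n = 40) {
  stopifnot(is.finite(R), R > 0, n >= 3)
  dr <- R / n
  r_face <- seq(0, R, length.out = n + 1)
  r <- (r_face[-1] + r_face[-(n + 1)]) / 2
  structure(
    list(n = n, R = R, dr = dr, r = r, r_face = r_face,
         area = 4 * pi * r_face^2,
         vol = 4 * pi / 3 * (r_face[-1]^3 - r_face[-(n + 1)]^3),
         xi = r / R),
    class = "radial_grid")
}

#' Volume integral of a radial field
#'
#' @param c Field values at cell centres.
#' @param grid A [radial_grid()].
#' @return The integral of `c` over the sphere volume.
#' @export
volume_integral <- function(c, grid) sum(c * grid$vol)

#' Volume average of a radial field
#'
#' @inheritParams volume_integral
#' @return The volume-weighted mean of `c`.
#' @export
volume_average <- function(c, grid) sum(c * grid$vol) / sum(grid$vol)

# Spherical diffusion operator in conservative finite-volume form.
# bc: "zero_flux" or "dirichlet" (ghost value c_out at the outer face).
# Returns dc/dt contribution (same length as c).
diffusion_op <- function(c, D, grid, bc = c("dirichlet", "zero_flux"),
                         c_out = 0) {
  bc <- match.arg(bc)
  n <- grid$n
  flux <- numeric(n + 1)                      # outward diffusive face fluxes
  flux[2:n] <- -D * grid$area[2:n] * diff(c) / grid$dr
  if (bc == "dirichlet")
    flux[n + 1] <- -D * grid$area[n + 1] * (c_out - c[n]) / (grid$dr / 2)
  (flux[1:n] - flux[2:(n + 1)]) / grid$vol
}

# Conservative upwind advection: -div(c v) with v given at faces
# (length n+1, v[1] = 0 by symmetry). Outer face uses upwind donor cell;
# for outflow the last cell value leaves the domain, for inflow c_out enters.
advection_op <- function(c, v_face, grid, c_out = 0) {
  n <- grid$n
  up <- ifelse(v_face[2:n] > 0, c[1:(n - 1)], c[2:n])
  flux <- numeric(n + 1)
  flux[2:n] <- grid$area[2:n] * v_face[2:n] * up
  vo <- v_face[n + 1]
  flux[n + 1] <- grid$area[n + 1] * vo * if (vo > 0) c[n] else c_out
  -(flux[2:(n + 1)] - flux[1:n]) / grid$vol
}

# Non-conservative upwind advective derivative w * dc/dr with w given at
# cell centres; used for the grid-motion correction on the normalized
# radial coordinate (fixed xi grid, moving boundary). The term +w dc/dr is
# transport with speed -w, so for w > 0 the stable one-sided difference is
# the forward one (information arrives from larger r).
grid_motion_op <- function(c, w, grid) {
  dcdr_bwd <- c(0, diff(c)) / grid$dr
  dcdr_fwd <- c(diff(c), 0) / grid$dr
  w * ifelse(w > 0, dcdr_fwd, dcdr_bwd)
}
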