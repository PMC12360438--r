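#' Cancer-cell population dynamics
#'
#' Local (per grid node) dynamics of the three cancer compartments —
#' non-stem (CC), stem-like (SCC) and treatment-induced (ICC) cells — with a
#' shared carrying capacity (densities normalized to 1):
#' \itemize{
#'   \item logistic proliferation at rate k1 * c_ox (oxygen-coupled), with a
#'     stemness factor on SCC;
#'   \item drug kill proportional to the internalized drug c_int, with
#'     reduced SCC susceptibility (stem-like resistance) and an
#'     oxygenation-dependent potency factor (reoxygenation
#'     chemo-sensitizes; hypoxic cells are partially protected);
#'   \item immune kill by NK cells, CD8+ effectors and tumoricidal M1
#'     macrophages (mass action), gated by the immunogenic-death
#'     activation level, scaled by oxygenation (hypoxia blunts cytotoxic
#'     function) and suppressed by Tregs and M2 macrophages;
#'   \item conservative interconversion flows SCC -> CC (differentiation)
#'     and drug-induced CC -> ICC.
#' }
#' Baseline cancer death is folded into the *net* proliferation coupling k1,
#' so with k1 = 0 and no treatment the populations are stationary.
#'
#' @param pops List of population density vectors (`cc`, `scc`, `icc`, `nk`,
#'   `t8`, `treg`, `m2` are used here).
#' @param c_ox Oxygen concentration vector, mol/m^3.
#' @param c_int Internalized drug concentration vector (dimensionless).
#' @param params Population parameter list (see [default_config()]
#'   `$populations`).
#' @return A list with derivative vectors `dcc`, `dscc`, `dicc` (per hour),
#'   `icd_rate` (drug-induced immunogenic death rate, density/h), and
#'   `net_growth` (total net cancer production, density/h, the volumetric
#'   growth source).
#' @export
cancer_rhs <- function(pops, c_ox, c_int, params) {
  p <- params
  C_tot <- pops$cc + pops$scc + pops$icc
  room <- pmax(1 - C_tot, 0)
  grow_cc <- p$k1 * c_ox * pops$cc * room
  grow_scc <- p$scc_growth_factor * p$k1 * c_ox * pops$scc * room
  grow_icc <- p$k1 * c_ox * pops$icc * room

  kill_act <- immune_activation(pops, c_int, c_ox, p)
  eff <- kill_act$effector_kill
  kill_cc <- eff * pops$cc
  kill_scc <- p$scc_kill_factor * eff * pops$scc
  kill_icc <- eff * pops$icc

  # hypoxic cells are partially protected from the chemotherapeutic payload
  pot <- p$drug_ox_floor + (1 - p$drug_ox_floor) * c_ox / p$c_host
  kd_cc <- pot * p$k_drug * c_int * pops$cc
  kd_scc <- p$scc_kill_factor * pot * p$k_drug * c_int * pops$scc
  kd_icc <- pot * p$k_drug * c_int * pops$icc
  conv <- p$k_conv * c_int * pops$cc          # drug-induced CC -> ICC
  diff_sc <- p$k_sc * pops$scc                # SCC -> CC differentiation

  dcc <- grow_cc - kill_cc - kd_cc - conv + diff_sc
  dscc <- grow_scc - kill_scc - kd_scc - diff_sc
  dicc <- grow_icc - kill_icc - kd_icc + conv
  icd <- kd_cc + kd_scc + kd_icc
  list(dcc = dcc, dscc = dscc, dicc = dicc, icd_rate = icd,
       net_growth = dcc + dscc + dicc)
}

# Immune cytotoxicity: effectors (NK, CD8+, tumoricidal M1 macrophages)
# kill only when activated — by ongoing drug-induced immunogenic cell death
# (antigen release) or by the persisting treatment-induced cancer cells,
# which remain immunologically visible after the drug clears. Tregs and M2
# macrophages suppress the effector activity, and hypoxia blunts cytotoxic
# function (kill scales with c_ox/c_host).
immune_activation <- function(pops, c_int, c_ox, p) {
  icd_proxy <- p$k_drug * c_int * (pops$cc + pops$scc + pops$icc) +
    p$k_icc_act * pops$icc
  act <- icd_proxy / (p$K_act + icd_proxy)
  sup <- 1 / (1 + p$s_treg * pops$treg + p$s_m2 * pops$m2)
  list(activation = act, suppression = sup,
       effector_kill = act * sup * (c_ox / p$c_host) *
         (p$k_nk * pops$nk + p$k_t8 * pops$t8 + p$k_m1 * pops$m1))
}

#' Immune-cell population dynamics
#'
#' Source/death dynamics for NK, CD8+, CD4+, regulatory T-cells and M1/M2
#' macrophages. Sources are scaled by local oxygenation (c_ox/c_host) and,
#' for effectors, boosted by immunogenic cell death; the CD8+ source and the
#' Treg mortality carry the checkpoint-inhibitor modulation computed by
#' [ici_pharmacodynamics()]. The M1/M2 pools additionally exchange through
#' the conservative polarization flux of [tam_polarization()].
#'
#' @param pops List of population density vectors.
#' @param c_ox Oxygen vector, mol/m^3.
#' @param ici List with `sigma_T8_eff` (vector) and `m_reg_eff` (scalar), as
#'   returned by [ici_pharmacodynamics()]; pass the baselines for no
#'   treatment.
#' @param icd_rate Drug-induced cancer death rate vector (density/h), from
#'   [cancer_rhs()].
#' @param vegf VEGF concentration vector (drives M2 polarization).
#' @param params Population parameter list.
#' @return A list of derivative vectors `dnk`, `dt8`, `dt4`, `dtreg`, `dm1`,
#'   `dm2` (per hour).
#' @export
immune_rhs <- function(pops, c_ox, ici, icd_rate, vegf, params) {
  p <- params
  w_ox <- c_ox / p$c_host
  recruit <- 1 + p$r_icd * icd_rate / (p$K_icd + icd_rate)
  dnk <- p$sigma_nk * w_ox * recruit - p$m_nk * pops$nk
  dt8 <- ici$sigma_T8_eff * w_ox * recruit - p$m_t8 * pops$t8
  dt4 <- p$sigma_t4 * w_ox - p$m_t4 * pops$t4
  dtreg <- p$sigma_treg * w_ox - ici$m_reg_eff * pops$treg
  pol <- tam_polarization(c_ox, vegf, pops$m1, pops$m2, p)
  dm1 <- p$sigma_m1 * w_ox - p$m_m1 * pops$m1 + pol
  dm2 <- p$sigma_m2 * w_ox - p$m_m2 * pops$m2 - pol
  list(dnk = dnk, dt8 = dt8, dt4 = dt4, dtreg = dtreg, dm1 = dm1, dm2 = dm2)
}

#' Macrophage polarization flux
#'
#' Net M2 -> M1 interconversion rate (density/h, positive toward M1). The
#' oxygen drive pushes M2 cells toward the immunostimulatory M1 phenotype as
#' oxygenation approaches the healthy reference; VEGF pushes M1 cells toward
#' the immunosuppressive M2 phenotype. Pure polarization conserves
#' m1 + m2 exactly.
#'
#' @param c_ox Oxygen vector, mol/m^3.
#' @param vegf VEGF concentration vector.
#' @param m1,m2 Macrophage density vectors.
#' @param params Population parameter list (`k_pol`, `h_vegf`, `K_vegf_pol`,
#'   `c_host`).
#' @return Net conversion flux vector (density/h).
#' @export
tam_polarization <- function(c_ox, vegf, m1, m2, params) {
  p <- params
  p$k_pol * ((c_ox / p$c_host) * m2 -
               p$h_vegf * vegf / (p$K_vegf_pol + vegf) * m1)
}

#' Endothelial-cell and angiogenic-factor dynamics
#'
#' Endothelial proliferation is driven by VEGF (saturating) and stabilized
#' by the angiopoietin balance Ang1/(Ang1 + Ang2 + eps); high Ang2
#' destabilizes vessels by shutting the proliferation term down. During
#' sonopermeation the proliferation and apoptosis terms are multiplied by
#' the wall-shear-stress factors, normalized by their zero-stress values so
#' that no-ultrasound dynamics equal baseline dynamics (the raw fitted
#' values are preserved by [proliferation_factor()]/[apoptosis_factor()]).
#' VEGF and Ang2 production rise with hypoxia; Ang1 is produced by the
#' stable vasculature itself.
#'
#' @param endo Endothelial density vector.
#' @param vegf,ang1,ang2 Angiogenic factor concentration vectors.
#' @param sono List with normalized factors `pr_n`, `ap_n` (1 outside
#'   ultrasound windows).
#' @param c_ox Oxygen vector, mol/m^3.
#' @param params Population parameter list.
#' @return A list of derivative vectors `dendo`, `dvegf`, `dang1`, `dang2`.
#' @export
vascular_rhs <- function(endo, vegf, ang1, ang2, sono, c_ox, params) {
  p <- params
  hyp <- pmax(1 - c_ox / p$c_host, 0)
  prolif <- p$k_pe * endo * pmax(1 - endo, 0) *
    vegf / (p$K_vegf + vegf) * ang1 / (ang1 + ang2 + p$ang_eps)
  death <- p$m_e * endo
  dendo <- sono$pr_n * prolif - sono$ap_n * death
  dvegf <- p$sigma_vegf * hyp - p$d_vegf * vegf
  dang2 <- p$sigma_ang2 * hyp - p$d_ang2 * ang2
  dang1 <- p$sigma_ang1 * endo - p$d_ang1 * ang1
  list(dendo = dendo, dvegf = dvegf, dang1 = dang1, dang2 = dang2)
}

#' Oxygen dynamics (full form)
#'
#' dc_ox/dt = D_ox lap c_ox + s (c_host - c_ox) - u c_ox with vascular
#' supply rate s proportional to the functional vascular density (relative
#' to its healthy-reference value) and first-order consumption u
#' proportional to the total metabolically active cell density. The outer
#' boundary is held at the healthy-tissue reference concentration.
#'
#' @param c_ox Oxygen vector, mol/m^3.
#' @param Sv_rel Functional vascular density relative to the healthy
#'   reference (dimensionless vector).
#' @param total_density Total cell density vector.
#' @param grid A [radial_grid()].
#' @param params Oxygen parameter list (`c_host`, `k_supply_per_h`,
#'   `k_consume_per_h`, `D_ox_m2_per_s`).
#' @return Derivative vector, mol/m^3 per hour.
#' @export
oxygen_rhs <- function(c_ox, Sv_rel, total_density, grid, params) {
  if (any(Sv_rel < 0)) stop("Sv must be >= 0", call. = FALSE)
  s <- params$k_supply_per_h * Sv_rel
  u <- params$k_consume_per_h * total_density
  diffusion_op(c_ox, params$D_ox_m2_per_s * 3600, grid, "dirichlet",
               c_out = params$c_host) +
    s * (params$c_host - c_ox) - u * c_ox
}

#' Quasi-static oxygen balance
#'
#' Fast-equilibration limit of [oxygen_rhs()] without diffusion: the local
#' algebraic balance c_ox = c_host * s/(s + u). With no consuming cells this
#' returns the healthy-tissue reference everywhere.
#'
#' @inheritParams oxygen_rhs
#' @return Oxygen concentration vector, mol/m^3.
#' @export
oxygen_steady <- function(Sv_rel, total_density, params) {
  s <- params$k_supply_per_h * Sv_rel
  u <- params$k_consume_per_h * total_density
  ifelse(s + u > 0, params$c_host * s / (s + u), params$c_host)
}

#' Hypoxia percentage
#'
#' 100 (1 - c_ox / c_host): the complement of tumor oxygenation relative to
#' the stable healthy-tissue oxygen level.
#'
#' @param c_ox Mean tumor oxygen concentration, mol/m^3.
#' @param c_host Healthy-tissue reference (default 0.2 mol/m^3).
#' @return Hypoxia percent in `[0, 100]`; concentrations above the reference
#'   are clamped to 0% with a warning.
#' @export
hypoxia_percent <- function(c_ox, c_host = 0.2) {
  if (any(c_ox < 0)) stop("c_ox must be >= 0", call. = FALSE)
  if (any(c_ox > c_host)) {
    warning("oxygen above host reference; hypoxia clamped to 0%",
            call. = FALSE)
    c_ox <- pmin(c_ox, c_host)
  }
  100 * (1 - c_ox / c_host)
}
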