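#' Default simulation configuration
#'
#' Returns the full nested parameter list driving [run_protocol()]. Values
#' printed in the source literature (pore-law coefficients, shear-stress
#' response quadratics, ketotifen halving/100x rules, oxygen reference,
#' protocol timing) are fixed; the remaining rates and moduli are declared
#' placeholder defaults chosen from standard literature ranges for murine
#' breast tumors, calibrated once so that an untreated tumor reaches the
#' ~150 mm^3 treatment trigger on the experimental timeline. Every entry can
#' be overridden via [load_config()] or by editing the returned list.
#'
#' Units: time in hours internally; population rates are per hour; drug
#' kinetic rates are per second (converted internally); lengths in metres
#' unless a key says otherwise.
#'
#' @return A nested list of class `sono_config`.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(
      initial_tumor_radius_mm = 2.29,   # ~50 mm^3 at inoculation
      n_radial_nodes = 40,
      host_domain_factor = 100          # host datum well beyond the tumor
    ),
    numerics = list(
      rtol = 1e-6, atol = 1e-9,
      output_cadence_h = 6,
      horizon_h = 720,                  # 30 days
      evolve_radius = TRUE,
      drug_bc = "dirichlet",            # host sink for diffusing species
      envelope = "rectangular",
      shear_prefactor = 1
    ),
    mechanics = list(
      host = list(shear_modulus_Pa = 500, bulk_modulus_Pa = 3000,
                  hydraulic_conductivity = 3e-13),
      tumor = list(shear_modulus_Pa = 1000, bulk_modulus_Pa = 5000,
                   hydraulic_conductivity = 1e-15),
      gamma_sigma = 0.15
    ),
    vasculature = list(
      Sv_ref_per_m = 2e4, endo_ref = 0.4,
      P_V_Pa = 2000, beta_c = 0.5, sigma_ref_Pa = 2000,
      Lp_base_m_per_Pa_s = 4e-12,
      pore_radius_base_nm = 200
    ),
    pore_law = list(
      quad_coeff = -14977.9087, lin_coeff = 8208.3947,
      const_coeff = -69.0722,
      baseline_pore_radius_nm = 200, max_pore_radius_nm = 1250
    ),
    sonopermeation = list(
      mechanical_index = 0.4, frequency_MHz = 1, effect_duration_h = 6
    ),
    microbubble = list(
      liquid_density = 1060, liquid_viscosity = 4e-3,
      wall_displacement_amplitude = 5e-8, equilibrium_radius = 1.7e-6
    ),
    ketotifen = list(
      ramp_duration_h = 72, daily_dose_mg_per_kg = 10
    ),
    drugs = list(
      doxil = list(name = "doxil", molecular_radius_nm = 45,
                   D_m2_per_s = 6e-12, D_free_m2_per_s = 1.6e-10,
                   k_el_per_s = 5.6e-6, k_int_per_s = 5.6e-5,
                   k_deg_per_s = 5.6e-6, alpha = 1, k_d_h = 24,
                   dose_mg_per_kg = 3, Per_base_m_per_s = 3e-11),
      anti_pd1 = list(name = "anti_pd1", molecular_radius_nm = 5,
                      D_m2_per_s = 1e-11, k_deg_per_s = 2.8e-6,
                      alpha = 1, k_d_h = 72, dose_mg_per_kg = 10,
                      Per_base_m_per_s = 1e-10),
      anti_ctla4 = list(dose_mg_per_kg = 5)
    ),
    ici = list(a_pd1 = 2, c_half = 0.05, a_ctla4 = 1.5, window_h = 96),
    oxygen = list(c_host = 0.2, k_supply_per_h = 10, k_consume_per_h = 15,
                  D_ox_m2_per_s = 2e-9, mode = "quasistatic"),
    populations = list(
      # initial densities (carrying capacity = 1)
      init = list(cc = 0.35, scc = 0.05, icc = 0, nk = 0.125, t8 = 0.15,
                  t4 = 0.2, treg = 0.15, m1 = 0.1, m2 = 0.2, endo = 0.4,
                  vegf = 0.1, ang1 = 0.15, ang2 = 0.1),
      # cancer kinetics (per hour)
      k1 = 0.5,                         # 1/(h (mol/m^3)); calibration target
      scc_growth_factor = 0.8, scc_kill_factor = 0.3,
      k_drug = 0.3, k_conv = 0.01, k_sc = 0.005, drug_ox_floor = 0.3,
      # immune kill and its regulation
      k_nk = 0.1, k_t8 = 0.35, k_m1 = 0.15, K_act = 0.002, k_icc_act = 0.02,
      s_treg = 3, s_m2 = 2,
      r_icd = 2, K_icd = 0.01,
      # immune sources/deaths (steady sigma/m at baseline)
      sigma_nk = 0.001, m_nk = 0.008,
      sigma_t8 = 0.0006, m_t8 = 0.004,
      sigma_t4 = 0.002, m_t4 = 0.01,
      sigma_treg = 0.0015, m_reg = 0.01,
      sigma_m1 = 0.0008, m_m1 = 0.008,
      sigma_m2 = 0.0016, m_m2 = 0.008,
      k_pol = 0.02, h_vegf = 1.5, K_vegf_pol = 0.2,
      # endothelium / angiogenic factors
      k_pe = 0.04, K_vegf = 0.1, m_e = 0.0025, ang_eps = 1e-3,
      sigma_vegf = 0.02, d_vegf = 0.05,
      sigma_ang1 = 0.02, d_ang1 = 0.05,
      sigma_ang2 = 0.02, d_ang2 = 0.05,
      c_host = 0.2
    ),
    schedule = list(
      trigger_volume_mm3 = 150,         # ketotifen starts at this volume
      fallback_day = 16,                # anchor if the trigger is not hit
      keto_to_sono_h = 72,              # sonopermeation 3 days after keto
      sono_to_nano_h = 1,               # nano-immunotherapy 1 h later
      cycle_gap_h = 72                  # second cycle 3 days later
    ),
    sweep = list(anchor_days = c(19, 22), intervals_h = c(1, 3, 6, 24)),
    report = list(time_h = 552)         # day 23 fold-change comparison point
  )
  class(cfg) <- c("sono_config", "list")
  cfg
}

#' Load a configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]: any key present
#' in the file overrides the default; absent keys keep their defaults.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @return A validated `sono_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
    class(cfg) <- c("sono_config", "list")
  }
  validate_config(cfg)
}

# recursive version of modifyList that preserves nested defaults
modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a configuration
#'
#' Checks the structural invariants the simulator relies on (positive
#' geometry and moduli, rates >= 0, reflection coefficients in range,
#' admissible pore bounds) and returns the config invisibly touched-up
#' (classes attached). Stops with an informative message on violation.
#'
#' @param cfg A configuration list.
#' @return The validated `sono_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  g <- cfg$geometry
  if (g$initial_tumor_radius_mm <= 0) stop("initial tumor radius must be > 0")
  if (g$n_radial_nodes < 5) stop("need at least 5 radial nodes")
  for (tis in c("host", "tumor")) {
    m <- cfg$mechanics[[tis]]
    if (any(unlist(m) <= 0))
      stop("mechanics for ", tis, " must be strictly positive")
  }
  pl <- cfg$pore_law
  if (pl$baseline_pore_radius_nm <= 0 ||
      pl$max_pore_radius_nm < pl$baseline_pore_radius_nm)
    stop("pore-law bounds invalid")
  if (cfg$sonopermeation$mechanical_index < 0 ||
      cfg$sonopermeation$frequency_MHz <= 0)
    stop("sonopermeation parameters invalid")
  if (any(unlist(cfg$microbubble) <= 0)) stop("microbubble parameters invalid")
  dox <- cfg$drugs$doxil
  if (dox$alpha < 1) stop("doxil alpha must be >= 1")
  rates <- c(dox$k_el_per_s, dox$k_int_per_s, dox$k_deg_per_s,
             cfg$drugs$anti_pd1$k_deg_per_s)
  if (any(rates < 0)) stop("drug rates must be >= 0")
  if (cfg$populations$k1 < 0) stop("k1 must be >= 0")
  if (cfg$oxygen$c_host <= 0) stop("oxygen reference must be > 0")
  class(cfg) <- unique(c("sono_config", class(cfg)))
  cfg
}

# small helpers used across modules
cfg_pore_law <- function(cfg) {
  pl <- cfg$pore_law
  pore_law(pl$quad_coeff, pl$lin_coeff, pl$const_coeff,
           pl$baseline_pore_radius_nm, pl$max_pore_radius_nm)
}

cfg_microbubble <- function(cfg) {
  mb <- cfg$microbubble
  microbubble_params(mb$liquid_density, mb$liquid_viscosity,
                     mb$wall_displacement_amplitude, mb$equilibrium_radius)
}

cfg_species <- function(cfg) {
  d <- cfg$drugs$doxil
  a <- cfg$drugs$anti_pd1
  list(
    doxil = drug_species("doxil", d$molecular_radius_nm, d$D_m2_per_s,
                         d$D_free_m2_per_s, d$k_el_per_s, d$k_int_per_s,
                         d$k_deg_per_s, d$alpha, d$k_d_h, d$dose_mg_per_kg),
    anti_pd1 = drug_species("anti_pd1", a$molecular_radius_nm, a$D_m2_per_s,
                            k_deg_per_s = a$k_deg_per_s, alpha = a$alpha,
                            k_d_h = a$k_d_h,
                            dose_mg_per_kg = a$dose_mg_per_kg))
}

cfg_base_wall <- function(cfg) {
  v <- cfg$vasculature
  sp <- cfg_species(cfg)
  lam <- function(s) min(s$molecular_radius_nm / v$pore_radius_base_nm, 1)
  h_d <- hindrance_coefficients(lam(sp$doxil))
  h_a <- hindrance_coefficients(lam(sp$anti_pd1))
  vessel_wall(
    pore_radius_nm = v$pore_radius_base_nm,
    Lp_m_per_Pa_s = v$Lp_base_m_per_Pa_s,
    P_V_Pa = v$P_V_Pa,
    Per_m_per_s = c(doxil = cfg$drugs$doxil$Per_base_m_per_s,
                    anti_pd1 = cfg$drugs$anti_pd1$Per_base_m_per_s),
    sigma_f = c(doxil = h_d$sigma_f, anti_pd1 = h_a$sigma_f))
}
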