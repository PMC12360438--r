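# Scaled-down configurations used across the suite: coarse radial grid and,
# where noted, shortened horizons. The scientific defaults themselves are
# untouched.

small_config <- function(n_nodes = 16, horizon_h = 720) {
  cfg <- default_config()
  cfg$geometry$n_radial_nodes <- n_nodes
  cfg$numerics$horizon_h <- horizon_h
  cfg
}

# closed-system transport configuration: no vessels, no boundary exchange,
# static domain
closed_config <- function(n_nodes = 12, horizon_h = 72) {
  cfg <- small_config(n_nodes, horizon_h)
  cfg$vasculature$Sv_ref_per_m <- 0
  cfg$numerics$drug_bc <- "zero_flux"
  cfg$numerics$evolve_radius <- FALSE
  cfg
}
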