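---
title: "Model and methods: mechanotherapy, sonopermeation and nano-immunotherapy in a spherical tumor"
author: "sonomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sonomech)
```

# Scope and geometry

`sonomech` simulates the response of a vascularized solid tumor to
combinations of a mechanotherapeutic agent (ketotifen), ultrasound
microbubble sonopermeation, and nano-immunotherapy (a liposomal
doxorubicin nanocarrier plus anti-PD-1 and anti-CTLA-4 checkpoint
antibodies). The tumor is a growing sphere; all fields are functions of the
radius only. The governing equations are discretized by a conservative
finite-volume method of lines on a fixed normalized radial grid
(`xi = r/R(t)`), with the moving boundary handled by a grid-motion
advective correction and the boundary speed set by the solid-phase velocity
at the rim, `dR/dt = v_s(R)`. A full 3-D finite-element treatment would add
nothing under spherical symmetry; the 1-D reduction is what makes the model
desk-scale.

The host tissue surrounding the tumor is not meshed. It enters through
boundary data: drugs see a well-perfused, well-cleared host (zero far
concentration), the interstitial pressure datum is zero at the rim, and
oxygen is held at the healthy reference at the boundary.

# State and couplings

Per radial node the model tracks four drug fields (nanocarrier `c_n`, free
chemotherapeutic `c_f`, internalized drug `c_int`, free anti-PD-1 antibody
`c_f_i`), ten cell populations (three cancer compartments CC/SCC/ICC, NK,
CD8+, CD4+, regulatory T-cells, M1/M2 macrophages, endothelium), three
angiogenic factors (VEGF, Ang1, Ang2) and the local growth stretch `J`.
Oxygen is quasi-static (below). Cell densities are normalized to the
carrying capacity; drug concentrations to the plasma peak of one bolus.

The causal chain the treatments exploit is:

* growth accumulates volumetric stretch `J`; solid stress
  `sigma_s = gamma_sigma (k + 4/3 mu) ln J` compresses vessels,
  `Sv = Sv_anatomic exp(-beta_c sigma_s/sigma_ref)`;
* functional vascular density `Sv` sets oxygen supply and the Starling
  exchange surface; interstitial fluid pressure solves
  `-div(k_th grad p_i) = L_p Sv (P_V - p_i)`, so high `L_p Sv / k_th`
  (alpha in the closed form) means IFP near vascular pressure and no
  convective delivery;
* ketotifen linearly halves the tumor moduli and multiplies `k_th` by 100
  over a 3-day ramp: stress (hence compression) falls and alpha collapses,
  so IFP drops and both perfusion and convective drug delivery rise;
* sonopermeation transiently (6 h by default) dilates vessel-wall pores
  per the fitted quadratic in acoustic pressure, which raises `L_p`
  (quadratic in pore radius) and the hindered permeability, and lowers the
  reflection coefficient; microstreaming shear stress additionally
  modulates endothelial proliferation/apoptosis through the fitted
  quadratics, normalized by their zero-stress values so that
  no-ultrasound dynamics are exactly baseline;
* internalized drug kills cancer cells and triggers immunogenic cell
  death, which activates NK/CD8+/M1 cytotoxicity (suppressed by Tregs and
  M2, blunted by hypoxia); the drug also converts a fraction of cancer
  cells into a treatment-induced compartment that stays immunologically
  visible, so effector activation persists after the drug clears;
  anti-PD-1 raises the CD8+ source with a saturating response to its local
  concentration; anti-CTLA-4 raises Treg mortality during a fixed
  post-dose window.

# Design choices where the problem was open

Several closures are deliberate package-level decisions:

* **Hindered transport.** Cylindrical-pore theory: partition
  `Phi = (1-lambda)^2`, diffusive hindrance
  `H = Phi (1 - 2.104 lambda + 2.089 lambda^3 - 0.948 lambda^5)`,
  reflection `sigma_f = 1 - (1-(1-Phi)^2) G(lambda)` with
  `G = 1 - (2/3) lambda^2 - 0.163 lambda^3`. The coefficients live in one
  function (`hindrance_coefficients`) so an alternative closure can be
  swapped.
* **Baseline pore radius 200 nm.** Tumor microvessels are leaky; a
  nanocarrier of 45 nm radius and an IgG-scale antibody must extravasate
  at a reduced rate even without ultrasound, otherwise the
  nano-immunotherapy-only arm would be inert, which contradicts the
  experiments the model is built to reproduce. The pore-dilation law is
  clamped to [200, 1250] nm: the fitted quadratic is negative at zero
  pressure and beyond ~0.55 MPa, where it has no physical reading.
* **Convection-limited nanocarrier delivery.** The Doxil wall
  permeability default (3e-11 m/s) is at the scale measured for ~100 nm
  liposomes, and the untreated tumor interstitium gets a dense-ECM
  hydraulic conductivity (1e-15 m^2/(Pa s)), putting the
  filtration-to-conduction ratio alpha near 30 at treatment size: IFP sits
  at vascular pressure almost everywhere and the carrier is starved of its
  convective route. Ketotifen's 100-fold conductivity increase is then
  literally a normalization to the healthy-tissue scale, and transvascular
  convection — not diffusion — is what it restores. Setting the
  permeability orders of magnitude higher (or the conductivity higher)
  silently converts the model to a regime where IFP hardly matters and the
  mechanotherapy effect disappears.
* **Pore-dilation rescaling.** During an ultrasound window `L_p` scales
  as `(r_o/r_b)^2` and the diffusive permeability as
  `H(lambda) (r_o/r_b)^2` — dilation at fixed pore number grows the open
  wall area. Rescaling the permeability by the hindrance factor alone
  (fixed areal fraction) makes sonopermeation self-defeating: the `L_p`
  surge drives IFP up to vascular pressure inside the window, shutting
  off convection with no compensating diffusive gain.
* **Immune-oxygen coupling.** Cytotoxic activity scales with
  `c_ox/c_host` and includes a tumoricidal M1 term; drug potency carries
  an oxygenation factor with floor 0.3 (hypoxic cells are partially
  protected). Both couplings implement the stated network directions
  (oxygenation supports immune activity; reoxygenation chemo-sensitizes)
  and are what make perfusion normalization therapeutically synergistic
  rather than purely growth-promoting.
* **Immune kill gating.** Baseline cancer death is folded into the net
  proliferation coupling `k1`, and effector kill is gated by
  drug-induced immunogenic cell death. Consequences: with `k1 = 0` an
  untreated tumor is exactly stationary, and monotherapies that do not
  deliver drug (ketotifen or ultrasound alone) do not notably shrink the
  tumor — both behaviours the in-vivo data show.
* **Anti-CTLA-4** is purely pharmacodynamic (96 h window of elevated Treg
  mortality after each dose); only anti-PD-1 is spatially transported.
* **Oxygen** is quasi-static: the local balance
  `c_ox = c_host s/(s+u)` with supply `s` proportional to relative
  functional vascular density and first-order consumption `u` proportional
  to total cell density. The full dynamic form (`oxygen_rhs`) exists for
  sensitivity checks; the quasi-static default removes the fastest time
  scale from the stiff system.
* **Rectangular ultrasound envelope** at full strength for the 6 h
  window (a linear-decay variant is available); overlapping windows take
  the maximum effect.

# Parameters

Printed, fixed quantities: the pore-radius quadratic
(−14977.9087, 8208.3947, −69.0722 in nm, MPa), the acoustic pressure
`p_ac = MI sqrt(fr)`, the proliferation/apoptosis response quadratics
(0.2533 and 0.6666 at zero stress), the ketotifen endpoint factors
(0.5, 100) over a 72 h ramp, the healthy-tissue oxygen 0.2 mol/m^3, the
protocol timing (treatment trigger near 150 mm^3, sonopermeation 3 days
after ketotifen start, injections 1 h after sonopermeation, a second cycle
3 days later, sweep anchors at days 19/22 with intervals 1/3/6/24 h) and
the mechanical-index range 0.2–0.6 (default MI 0.4 at 1 MHz).

Everything else — tissue moduli, hydraulic conductivities, vascular
geometry, transport and population rate constants — is a declared
placeholder default in `default_config()`, chosen once from standard
literature ranges for murine breast tumors and calibrated so an untreated
tumor passes the ~150 mm^3 trigger on the experimental timeline. `k1`, the
oxygen-proliferation coupling, is the single tumor-line-specific parameter;
`calibrate_k1()` root-finds it against the final control volume of a
measurement table and holds it fixed across arms.

# Numerics

* Conservative finite volumes on equal-width shells; first-order upwind
  advection (fluid velocity for interstitial species, solid velocity for
  internalized drug and cells); harmonic-mean face conductivities in the
  elliptic IFP solve (sparse tridiagonal factorization).
* Quasi-static quantities (stress, `Sv`, IFP, fluid velocity, oxygen,
  ultrasound and ramp factors, wall coefficients) are frozen over each
  output segment (default 6 h) and at every scheduled event boundary,
  where the stiff integrator (lsoda, rtol 1e-6, atol 1e-9) is restarted.
* The state is interleaved node-major so the integrator can factor a
  banded Jacobian (half-bandwidth `2*nfields - 1`); the weak global
  couplings (boundary speed, solid-velocity integral, quadrature states)
  are intentionally excluded from the band. They affect only Newton
  convergence rate, not accuracy.
* Two quadrature states track cumulative degraded payload and
  time-integrated mean internalized drug; the former turns the
  closed-system mass-balance check into an identity limited only by
  integrator tolerance, the latter is the exposure metric of the
  scheduling sweep.
* Degenerate inputs: the raw pore law is clamped to its physical range;
  hindrance ratios above 1 mean full exclusion; negative concentrations
  from solver overshoot are clamped inside rate evaluations only.

# Problem sizes

Production defaults use 40 radial nodes over a 30-day horizon. The
package's own test suite and examples run the same model scaled down — 10
to 16 nodes — which changes final volumes by well under the 1% grid
convergence bound checked on the control arm (100 vs 200 nodes).

# The synthetic measurement generator

`generate_fixture()` emulates caliper growth-curve data: it samples a
simulated volume trajectory every 2–4 days and applies multiplicative
log-normal noise with a chosen coefficient of variation (default 10%,
8 replicates), deterministic under a seed. It reproduces measurement
noise and sampling cadence, but not animal-to-animal growth-rate
heterogeneity, group dropout, or caliper bias; a passing calibration
recovery on fixtures therefore demonstrates identifiability of `k1` under
measurement noise, not robustness to biological variation.

# Known limitations

A scheduling subtlety worth knowing: with the fixed day-19/22 anchors of
the order/interval analysis, the second ultrasound application opens the
vessel wall while part of the *first* dose is still circulating. That
residual is larger when the injection trails the pulse by 24 h (48 h gap
to the second pulse) than by 6 h (66 h gap), so in the sono-first order
the per-cell exposure at the 24 h interval comes out a few percent above
the 6 h interval instead of below it. The effect is a real consequence of
mono-exponential plasma decay (time constant 24 h) combined with the
repeated-cycle protocol, not a numerical artifact; the corresponding
monotonicity check in the test suite documents it as a known failure.

* No acoustic wave physics: the pulse is a spatially uniform pressure with
  a fitted biological response; no attenuation, scattering or cavitation.
* The solid mechanics is a scalar growth-stress law, not tensorial
  poroelasticity; it preserves the two couplings that matter here
  (softening lowers stress and decompresses vessels; conductivity lowers
  IFP).
* Immune closure uses the simplest mass-action/saturation forms honoring
  the stated interaction directions; rate constants are not fitted to
  immunophenotyping data.
* Plasma pharmacokinetics is a mono-exponential bolus with superposition
  capped at the plasma ceiling; no protein binding, no explicit lymphatics
  (folded into degradation and the host sink).
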