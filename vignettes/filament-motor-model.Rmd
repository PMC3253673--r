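---
title: "A discrete filament-motor model of confined active gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete filament-motor model of confined active gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activegel)
```

## The model

`activegel` simulates a minimal cytoskeleton: `N` semiflexible polar
filaments and the two-headed motor proteins that cross-link them, confined
to a quasi-two-dimensional cylindrical box whose curved wall is squeezed by
an external pressure. Despite its simplicity this system self-organises
into the structures seen in microtubule–kinesin assays and in dividing
yeast cells: asters, semi-asters, bipolar spindles, nematic arrangements
and transiently rotating vortices.

**Filaments.** Each filament is a bead–spring chain of `M` monomers at bond
length `b` (the length unit). Bonds are Hookean with spring constant
`k_bond = 100 kT/b^2`; curvature elasticity `U = (kappa/b) * sum(1 - cos
theta)` over joints with `kappa = 200 b kT` gives a worm-like chain with
persistence length `l_p = kappa/kT = 200 b = 20 L / 3` for the default
`M = 30`. Self-avoidance and all wall–monomer interactions use the
repulsive (WCA) Lennard-Jones potential with diameter `sigma = b` and
`eps = 5 kT`; only directly bonded neighbours are excluded from it.
Monomer 1 is the minus end, monomer `M` the plus end: this index
convention is fixed here (the direction of motor stepping defines which
end is which) and used everywhere.

**Motors.** Only motors bridging two different filaments are explicit; the
free-motor pool is assumed uniform and folded into the attachment rate. A
motor is a zero-rest-length Hookean spring (`k_motor = kT/b^2`) whose two
heads sit on monomers of different filaments. Four rates define the
kinetics, all applied per kinetics interval `dt_k`:

* attachment `k_A`, per monomer pair on different filaments within the
  capture radius `2^(1/6) sigma` (so `k_A` is a molecular rate times the
  free motor concentration);
* detachment `k_D` per head; either head detaching removes the motor;
* stepping `k_M` per head towards the plus end, attenuated by the
  Boltzmann factor `exp(-dE/kT)` of the trial move's spring-energy change
  (clipped at probability 1 for downhill moves);
* end detachment `k_E`, which *replaces* `k_D` for a head dwelling at the
  plus end. `k_E = k_D` unless stated.

Within one sweep the order is attach, then move (heads visited in random
order), then detach. Multiple motors may share a monomer; there is no
exclusion between motor heads.

**Confinement.** Two planar walls at `z = 0` and `z = Z = 5 b` make the
box quasi-two-dimensional while still allowing filaments to cross. The
curved boundary is a polygon of `n_wall = 80` nodes with reference spacing
`l_0`. Spacing changes cost `c_stretch * kT * Z * dl^2 / l_0^3` per node
pair (`c_stretch = 1/2`) and discrete-curvature changes cost
`c_bend * kT * l_0 * Z * dkappa^2` per triplet (`c_bend = 10^3`), with the
discrete curvature defined as turning angle over `l_0` and its reference
`kappa_0 = 2 pi / (n_wall l_0)`. The wall couples to an external pressure
through a `P V` term, `V` being the shoelace polygon area times `Z`.

**Dynamics.** Monomers follow overdamped Brownian dynamics with
slender-body anisotropic drag: friction `gamma` along the local tangent
and `2 gamma` perpendicular to it, i.e. mobility
`M_i = t t'/gamma + (I - t t')/(2 gamma)` with `t` the normalised mean of
the adjacent bond directions. Noise obeys fluctuation–dissipation with
this mobility. Wall nodes have no Brownian dynamics; they move by
Metropolis Monte Carlo on their `(x, y)` coordinates, one uniform trial of
half-width `delta_wall` per node per sweep in random order, with the
energy including wall elasticity, wall–monomer repulsion and `P V`. In
fixed-volume mode the wall is instead an analytic rigid circle whose
radius follows an imposed schedule, and wall MC is skipped.

**Units and normalisations.** Energies are in `kT`, lengths in `b`, time
in `gamma b^2 / kT`. Results are reported against the normalised motor
rates `k_A / k_D` and `k_M tau_b`, where `tau_b = L b gamma / (4 kT)` is
the time for a filament to diffuse one monomer spacing, and the pressure
against `P_0 = eps / b^3`. Mapping `b = 10` nm (between actin and
microtubule diameters) gives a force unit `kT/b` of about 0.41 pN and a
default filament length of 0.3 µm (`physical_units()`).

## The initial condition

`init_configuration()` places all filaments straight and radial with plus
ends pointing inward — a prepared aster — in three layers at heights `b`,
`Z/2` and `Z - b`, split as evenly as possible (for `N = 175`:
59/58/58). Azimuthal positions are equally spaced with a random jitter and
per-layer phase, so different seeds give statistically equivalent starts
that do not predispose a rotation direction. The radial span keeps every
monomer at least `2 b` from the wall; `R0 > L + 3 b` is required.

## Order parameters and statistics

**Polarity modes.** Each filament contributes a unit polarity vector (the
x–y projection of its minus-to-plus end-to-end vector; vertical filaments
are skipped). The mean polarity conditioned on the azimuthal angle of the
centre of mass around the system centre (the wall-node centroid) defines a
field `p(theta)`, estimated on `n_bins` angular bins, with empty bins
contributing zero and bin means deliberately *not* renormalised — a bin of
opposing filaments should cancel. Its angular Fourier coefficients give
rotation-invariant amplitudes `Q_m = (|a_m|^2 + |b_m|^2) / (2 pi^2)`,
`m = 0..3`. Choose `n_bins` no larger than about `N/4`: the zero-fill
convention deflates amplitudes when bins are mostly empty (the package
defaults to 40 bins for the full `N = 175`).

**Classification.** The measured `(Q_0..Q_3)` is assigned to the nearest
(Euclidean) of four ideal-state targets: aster `(0, 1, 0, 0)`, nematic
`(0, 0, 0, 0)`, spindle and semi-aster. Two target sets ship with the
package because the commonly quoted closed forms disagree with direct
quadrature of the defining fields in two places: the semi-aster `Q_2`
evaluates to `333/(1225 pi^2)` rather than `333/(1715 pi^2)`, and the
spindle `(Q_1, Q_3)` to exactly half the quoted `(2/pi^2 + 1/2, 2/pi^2)`.
`ideal_state_targets("printed")` (the default for classification, to keep
state-diagram boundaries comparable with the quoted values) and
`ideal_state_targets("derived")` (the quadrature values) are both
available. One consequence worth knowing: under the printed targets a
*pure* spindle field is equidistant between "spindle" and "nematic", so
classification of weakly polarised spindles is more robust under the
derived set. Ties break deterministically in the order spindle, aster,
nematic, semi-aster.

**Vorticity.** Collective rotation is measured by the filament-averaged
transverse velocity `(v x p)_z = v_x p_y - v_y p_x` (centred finite
differences of the centre of mass over one frame interval; units of
`b/tau_b`, the characteristic filament velocity). For a run, `V = |mu| /
sigma` of this series from `t = 0` up to the contraction time; the mean
over replicates above the conventional threshold 0.7 marks a vortex. The
signed values feed a direction histogram and an exact two-sided binomial
test of direction symmetry.

**Contraction.** The system radius (mean wall-node distance from the
wall-node centroid) is fit to the four-parameter hyperbolic tangent
`R(t) = R_min + dR * tanh((t - t_cont)/dt_width)` by Levenberg–Marquardt
least squares. Initial guesses are level-based (head/tail means set the
offset and the signed amplitude, the steepest slope locates `t_cont`).
When the fitted `|dR|` is below three residual standard deviations, or
`t_cont` falls outside the observed span, or the fit fails, the run is
declared uncontracted and `t_cont` is assigned the configured maximum
time.

**MSAD.** The mean-squared angular displacement of centre-of-mass angles
about the system centre, unwrapped per filament (frame increments mapped
to `(-pi, pi]`) and averaged over all waiting times up to `t_cont`,
distinguishes angular diffusion (`2 D dt`, log–log slope 1) from coherent
rotation (`(omega dt)^2`, slope 2).

**Lifetime statistics.** Contraction times (and switching intervals of
fixed-volume vortices, extracted as sign changes of a boxcar-smoothed
transverse-velocity series) are tested against two hypotheses: an
exponential with unknown mean (contraction at a fixed *rate* — a Poisson
process) and a normal with unknown mean and variance (a fixed *time*).
Both use the Anderson–Darling `A^2` with estimated parameters; since the
null distribution of `A^2` with estimation is not standard, p-values come
from a seeded parametric bootstrap (default `10^4` resamples,
re-estimating parameters per resample). The normal-case statistic is
cross-checked against an independent implementation in the test suite,
and the bootstrap p-values are verified to be uniform under the null.

## Synthetic-data generators

The `gen_*` fixtures make every analysis function testable without the
simulator: ideal polarity fields with optional angular noise (apolar
regions realised as antiparallel unit-vector pairs, since real filaments
always carry unit polarity), rigidly rotating and angularly diffusing
rings, exact tanh radius curves plus Gaussian noise, and exponential or
normal lifetime samples. They emulate the *kinematics* that the analysis
layer measures — not bond-scale mechanics, excluded volume or motor
occupancy. A passing analysis suite therefore certifies the estimators,
not the physics; the physics is exercised separately by the property
tests (force–gradient consistency, fluctuation–dissipation, Boltzmann
sampling of the wall, motor master-equation occupancy, worm-like-chain
persistence).

## Numerical choices

* `dt = 5e-4 gamma b^2/kT`, about a tenth of the stiffest spring's
  relaxation time. Per-step displacements are additionally capped at
  `max_disp = 0.25 b`: the prepared aster can start with inner-ring
  monomers inside the steep part of the WCA potential (the paper-scale
  inner ring sits near contact spacing by construction), and without a cap
  a single overshoot there is catastrophic; with it, overlaps relax over a
  few steps while ordinary thermal steps (~0.03 b) are untouched. Being a first-order
  Euler–Maruyama scheme, it slightly inflates the variance of the
  stiffest modes; at `dt = 5e-4` this biases a fitted persistence length
  roughly 10% low, so the worm-like-chain recovery test integrates at
  `dt = 2e-4` where the bias is within the statistical tolerance.
  Structural observables (`Q_m`, motor counts) are insensitive at these
  step sizes.
* Motor kinetics and wall MC run every 10 BD steps; event probabilities
  `k * dt_k` stay well below 1 for all rates considered. The excluded
  volume/attachment neighbour list (cell list, cutoff plus a `0.5 b`
  skin) is rebuilt on the same stride.
* Wall trial step `delta_wall = 0.1 b` by default. Note a physical
  limitation of single-node Metropolis dynamics: contraction of the ring
  under pressure is a collective mode, so the wall contracts slowly and —
  under a strong pressure quench — can transiently arrest in slightly
  rippled shapes. The wall equilibrium tests therefore use a smaller
  trial step and, for the filament-free contraction claim, a comparison
  against the radius reached with a filament gel inside.
* Three independent xoshiro256++ streams (thermal noise, motor kinetics,
  wall moves) derive from the single run seed, so activating one
  subsystem never perturbs another's draw sequence; runs are bit
  reproducible from the seed.
* Degenerate cases: coincident bonded monomers raise an error (the bond
  direction is undefined); a vanishing local tangent falls back to
  isotropic drag `1/(2 gamma)` with a warning; a zero-variance vorticity
  series reports `V = Inf` with a diagnostic rather than `NaN`.

## Test problem sizes

The shipped tests are sized for a single CPU: persistence-length recovery
uses 15 non-interacting `M = 20` chains sampled over ~50 diffusion times;
the state-tendency checks use `N = 40, M = 10` in an `R0 = 13.5 b` box for
80 `gamma b^2/kT` with seed-paired low/high attachment runs (pairing
removes most initial-condition variance and the assertions are
direction-only — with filaments this short the collective states are
weaker than at full scale, where vortices in particular require `M = 30`
and thousands of `tau_b`). Full-scale state diagrams need replicated runs
of order `10^4 tau_b` and are out of desk scope.

## Limitations

No hydrodynamic coupling beyond the local anisotropic drag; fixed filament
lengths (no growth or treadmilling); no motor-head exclusion; the wall has
no inertia and its MC dynamics is not a physical relaxation time; vortex
states at full scale are only one filament in radius, so continuum
comparisons are out of scope.

## A minimal session

```{r example, eval = FALSE}
p <- gel_params(N = 40, M = 10, R0 = 13.5, n_wall = 44,
                k_A = 0.15, k_D = 0.005, k_M = 0.015,
                t_end = 40, frame_interval = 2000)
tr <- run_simulation(p, seed = 1, n_bins = 8)
glance(tr)
autoplot(tr)

fit <- fit_contraction(tr$observables[, c("time", "radius")])
glance(fit)

v <- transverse_velocity(tidy(tr), v_scale = p$b / p$tau_b)
vorticity_stats(v, t_cont = glance(fit)$t_cont)
```
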