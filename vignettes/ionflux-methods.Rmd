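---
title: "Finite-field ion transport analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-field ion transport analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionflux)
```

# The problem

When a homogeneous electric field is applied to an electrolyte, the cation
drifts, and its mean current density in the linear regime defines the ionic
conductivity. How the ion moves — dragging an intact first solvation shell
(*vehicular* transport) or hopping between solvent cages while its ligands
constantly exchange (*structural* transport) — is encoded in the joint
statistics of the shell-member identities and the instantaneous current.
`ionflux` implements the full analysis chain for this question on molecular
dynamics trajectories: field-coupled forces from atomic polar tensors,
solvation-shell structure and kinetics, Green–Kubo and finite-field
conductivities, and the decomposition of the ionic current into vehicular and
structural contributions.

# Field coupling through atomic polar tensors

In a perturbative treatment of a homogeneous field $\varepsilon$, the total
force on atom $i$ splits into an unperturbed part and a field-induced part

$$F_{i,\eta} = F^0_{i,\eta} + \sum_\zeta P_{i,\eta\zeta}\,\varepsilon_\zeta,$$

where $P_i$ is the atom's *atomic polar tensor* (APT): the derivative of the
system dipole with respect to the atom's position, equivalently the
derivative of the atomic force with respect to the field. The treatment is
first order in the field; no polarizability (second-order) terms are
included, and `check_field()` rejects magnitudes above 0.3 V/Å where the
linearization would be meaningless. One third of the APT trace is the Born
effective charge; the acoustic sum rule demands
$\sum_i P_i = q_\mathrm{tot}\,\mathbb{I}$. Tensors estimated numerically
(or by regression models) violate the rule slightly, so `apply_sum_rule()`
subtracts an equal share of the deviation from every atom — the plain
arithmetic split, not a mass- or species-weighted one — which restores the
identity to machine precision and guarantees that the net field force on the
system is exactly $q_\mathrm{tot}\varepsilon$. The correction is applied once
per tensor table at load time (`read_apt_table()`), not per frame.

`finite_difference_apt()` closes the loop: it recovers APTs from any force
model by central differences in the field, with a default increment of
0.0257 V/Å. Central (rather than forward) differences cost the same number
of force evaluations per axis and are second-order accurate; on an exactly
linear force model they reproduce the generating tensors to round-off, which
the tests exploit as an oracle.

Units are kept native throughout: length in Å, time in fs, energy in eV,
charge in e, fields in V/Å. A force of 1 e·V/Å is numerically 1 eV/Å, so the
contraction above needs no conversion factor; all remaining conversions are
centralized in `transport_constants()`.

# The toy electrolyte

Real finite-field simulations of this kind require machine-learned
potentials. To make the analysis chain testable end to end, the package
ships a self-contained finite-field Langevin simulator
(`simulate_electrolyte()`): one cation in a bath of single-site
Lennard-Jones solvent particles, each carrying a rigid point dipole.

**What it emulates.** The three statistical features the analyses rely on:
(1) a distinct, exchangeable first solvation shell whose exchange rate is
tunable through the ion–solvent well depth; (2) solvent dipole orientations
that align with the external field and with the ion's Coulomb field, so the
tilt-angle analysis has structure to find; (3) steady-state drift of the ion
under a homogeneous field, with the Joule heat removed by the Langevin
friction so the kinetic temperature stays within a few percent of target.

**What it does not emulate.** Water chemistry: there are no hydrogens, no
hydrogen-bond network, no Ewald electrostatics (charge–dipole torques are
cutoff-based), and translational ion–solvent attraction is purely
Lennard-Jones. Absolute conductivities, lifetimes and coordination numbers
are therefore *not* comparable to any real alkali cation; what carries over
is the statistical structure. Passing tests demonstrate that the estimators
recover known inputs and satisfy exact identities — not that the toy fluid
reproduces water.

**Dynamics.** Translations use the BAOAB splitting of Langevin dynamics with
a 1 fs default timestep. Dipole orientations follow overdamped rotational
Brownian motion on the unit sphere whose stationary distribution is
Boltzmann in the dipole–field energy; the rotational diffusion constant
derives from a water-like moment of inertia (0.64 amu Å²) and the rotational
friction. The solvent carries zero net Born charge, so the field exerts no
net translational force on it; the ion couples through the Born-charge
tensor $q\,\mathbb{I}$. Positions are stored unwrapped — diffusion and
drift analyses need continuous displacements — and minimum-image convention
is applied only inside the force loop, with pair cutoffs of $2.5\sigma$
capped just below half the box.

**Parameters that matter.**

| parameter | default | why |
|---|---|---|
| solvent $\sigma_{ss}, \epsilon_{ss}$ | 3.166 Å, 0.00674 eV | SPC/E-like liquid at 300 K |
| number density | 0.0334 Å⁻³ | water-like packing |
| ion presets li/na/cs | $\sigma_{is}$ = 2.0/2.6/3.2 Å, $\epsilon_{is}$ = 0.400/0.105/0.022 eV | see below |
| $\gamma_t$ | 0.01 fs⁻¹ | ~100 fs velocity relaxation; doubles as Joule heat sink |
| $\gamma_r$ | 0.1 fs⁻¹ | dipole reorientation on the 100 fs scale |
| dipole moment | 0.489 e·Å | water-like (2.35 D) |
| timestep | 1 fs | ≥ 80 steps per cage-vibration period for the stiffest preset |

The three ion presets realize the strong/intermediate/weak coordination
archetypes. Their well depths were chosen so that the zero-field continuous
shell lifetimes separate — on the order of 9–13 ps for the li-like preset
versus 3–5 ps for the na- and cs-like ones at 300 K in a 100-solvent box —
mirroring the strong-to-weak ordering of small-to-large alkali cations,
while keeping all three measurable within tens of picoseconds of
simulation. The `well_depth_mult` configuration knob scans between the
regimes continuously on any preset; the shell lifetime increases strictly
with it. The deep li-like well also produces a
sharp cage ("rattling") mode near 60 fs, whereas the cs-like ion is
quasi-free: its spectrum has no resolvable low-frequency peak, which is the
physically expected signature of purely structural transport.

The stochastic state generator `markov_cn_series()` complements the
simulator with an *exact* oracle: piecewise-constant coordination states
with exponential dwell times, per-member Poisson exchange, and per-state
Gaussian drift velocities, all with recorded ground truth. Survival,
histogram, and decomposition estimators are validated against it.

# Solvation structure

The radial distribution function uses 0.03 Å bins by default and standard
shell-volume normalization; the running coordination number is the
cumulative mean pair count, which equals the $4\pi\rho\int g\,s^2\,ds$
integral evaluated with the same binning. The first-shell radius $R_0$ is
the first local minimum of $g(r)$ after its first peak. Because the minimum
flattens for weakly bound shells, the raw-bin argmin is noise-dominated;
`detect_first_minimum()` therefore smooths with a Savitzky–Golay filter
(11 bins, order 3) and searches from the peak out to 1.8× the peak position,
raising an error (rather than guessing) when the curve is monotone. The
zero-field $R_0$ is reused at finite fields by convention, so that changes
in occupancy are not confounded with changes of the boundary.

The smooth coordination number is the rational switching function
$\mathrm{CN} = \sum_j (1-(r_j/R_0)^{20})/(1-(r_j/R_0)^{40})$, whose
removable singularity at $r_j = R_0$ is evaluated by its limit $1/2$. The
potential of mean force along CN is $-k_BT\ln p(\mathrm{CN})$ on a 0.1-CN
grid, with the additive constant fixed by $\min \mathrm{PMF} = 0$ and empty
bins reported as `NA` rather than zero. Integer membership uses strict
inequality $r < R_0$; ties at exactly $R_0$ are outside.

The tilt-angle analysis accumulates, for each first-shell member,
$\cos\alpha$ (member→ion direction against the field) and $\cos\theta$
(member dipole against the field), *conditional on membership* — which
avoids the solid-angle weighting that a joint distribution of the raw
angles would suffer. Members with $\cos\alpha<0$ lead the drifting ion,
$\cos\alpha>0$ trail it; the class means of $\cos\theta$ are reported with
their angle conversions.

# Shell kinetics and transport

**Survival.** The continuous survival correlation $C(\tau)$ counts, per time
origin, the fraction of current shell members that remain inside $R_0$ at
*every* intermediate frame ($t^\ast = 0$: no return allowance, since
intermittent variants are sensitive to the chosen re-entry window). The
per-origin ratio $S/N$ is averaged over origins; origins are restricted to
those with the full lag window available, which makes the origin set
identical at every lag and hence $C$ exactly non-increasing with $C(0)=1$.
The continuous lifetime $\tau_c$ is the trapezoidal integral of $C$ over the
available lag range (default: half the series).

**Diffusion.** The VACF is the multi-origin velocity autocorrelation
(FFT-based); the Green–Kubo diffusion constant integrates it to 2.5 ps, after
which the integral is converged for every system studied here. Uncertainty
follows the segment-bootstrap design: the trajectory is cut into 20 ps
segments, D is estimated per segment, and 10,000 resampled means give the
estimate and its spread. `finite_size_extrapolation()` performs the weighted
$D$ vs $1/L$ fit whose intercept is the infinite-dilution constant, and
`nernst_einstein()` converts to molar conductivity
$\Lambda_m = F^2 D_\infty / RT$. An independent Einstein-route estimator
(`einstein_msd_diffusion()`, FFT MSD decomposition) cross-checks the
Green–Kubo value in the tests; on the toy system the two agree to better
than a percent.

**VDOS and the rattling period.** The velocity density of states is a
Hann-windowed periodogram averaged over blocks (several block counts are
computed so peak stability against blocking can be checked; the
most-averaged spectrum is the reference). The windowed periodogram is the
Wiener–Khinchin pair of the block VACF and is manifestly non-negative. The
rattling frequency is the lowest interior local maximum: the zero-frequency
bin is excluded (drift and diffusion contaminate it), the spectrum is
lightly smoothed, and a candidate peak must both rise above its surrounding
minima by 20% of the spectral maximum and stand at least 1.5× above the
median level — near-flat spectra (free particles, white noise) are rejected
with an error demanding a manual period instead of returning a noise bump.

**Conductivity.** The instantaneous ionic current density is
$J_{\mathrm{ion},z} = V^{-1}\sum_\eta P_{\mathrm{ion},\eta z}\,
v_{\mathrm{ion},\eta}$ — only the z-column of the ion's APT enters. Per
field stage, the steady-state mean and a block-averaged standard error are
formed after discarding 20 ps of equilibration; block length grows until the
blocked SEM changes by less than 5% over two successive doublings, and if no
plateau is reached before fewer than 8 blocks remain the largest-block value
is reported with a warning. The conductivity is the slope of a
zero-intercept least-squares fit of $\langle J\rangle$ against $E_z$,
restricted to the linear regime (default cutoff 0.0514 V/Å) and weighted by
$1/\mathrm{SEM}^2$ — the weighting is this package's choice; an unweighted
zero-intercept fit is recovered by passing equal SEMs. The per-frame ion APT
defaults to a static table value; a `per_frame_apt` hook accepts
frame-resolved tensors when a simulation provides them.

# Vehicular/structural decomposition

A segment is a maximal run of frames with an *unchanged shell identity set*;
any exit, entry, or count-preserving swap ends it. This identity-based rule
is deliberately stricter than tracking the coordination count alone: a
swapped ligand means the cage has been broken even if $n$ is unchanged.
Segments lasting at least one rattling period are stable-$n$ (vehicular);
all frames of shorter segments are labile (structural). Whole segments are
labeled — frames near the end of a qualifying segment count as stable, since
stability is a property of the segment, not of frame margins. Every observed
$n$ gets its own class. The per-class time weights and mean current
densities satisfy $\sum_c w_c \langle J\rangle_c = \langle J\rangle$ exactly
(an algebraic identity the tests assert at machine precision), and
`sensitivity_scan()` re-runs the decomposition at multiples of the rattling
period, verifying that the vehicular weight can only shrink as the
stability threshold grows.

# Problem sizes used in the checks

The package's own validation runs were sized as follows: the
fluctuation–dissipation closure uses 200 solvent particles with a 250 ps
zero-field trajectory and five 150 ps field stages at 0.01–0.05 V/Å (about
10⁶ steps); the transport-regime comparison uses 100 solvent particles with
60–80 ps zero-field trajectories per ion preset; estimator oracles use 10⁵
Markov frames (survival), 10⁶ samples (PMF recovery), and 4–6 × 10⁵ steps
(free-particle Langevin). The closure is asserted within twice the combined
bootstrap/regression standard error, which is the honest resolution of runs
of this length.

# Known limitations

* Cutoff electrostatics and single-site solvent: dielectric screening of the
  ion's field is absent, so dipole alignment near the ion is stronger than
  in a real polar solvent.
* The Langevin thermostat damps hydrodynamic momentum transfer; diffusion
  constants depend on the chosen friction and are not meant to match
  experimental values.
* The survival estimator's origin restriction trades lag range for exact
  monotonicity; lifetimes longer than about half the trajectory are
  truncated by construction (the $\tau_c$ of a non-decaying shell equals the
  lag range).
* Cubic boxes only; no binary trajectory formats in this version.
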