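---
title: "Gradient-free surrogate dynamics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-free surrogate dynamics: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfnamd)
```

## The problem

Trajectory surface hopping needs, at every time step, the energies of
several electronic states and the force on the active state.  For many
high-accuracy electronic-structure methods analytic gradients are not
available, and numerical differentiation multiplies the cost by the
number of degrees of freedom.  The workaround implemented here is to
fit a differentiable surrogate to *energies only* and to obtain forces
by differentiating the surrogate analytically.  Everything in this
package exists to exercise that protocol end to end: analytic
multi-state model potentials play the role of the reference electronic
structure, a multi-fidelity feed-forward surrogate is trained on their
energies, and a coupling-free surface-hopping engine propagates
ensembles on either.

Everything internal is in Hartree atomic units (hartree, bohr, atomic
time, hbar = 1); femtoseconds and angstroms appear only at file
boundaries and in analysis output.

## Model systems

Three diabatic models ship with the package.  Diagonalizing the
diabatic matrix V(x) gives the adiabatic surfaces; Hellmann-Feynman
contraction of dV/dx gives the per-state gradients.  At a conical
intersection the eigenbasis is not unique; `evaluate_adiabatic()`
returns one-sided gradients and sets a `degenerate` flag rather than
raising, because the seam optimizer must be able to evaluate there.

* **`model_linear_crossing()`** — two diabats with slopes ±F crossing at
  x = 0 under a constant coupling H12 (defaults F = 0.01 hartree/bohr,
  H12 = 0.005 hartree, mass 2000 a.u.).  A constant-velocity passage has
  the closed-form Landau–Zener transition probability
  P = exp(−2π·H12²/(ħ·v·|ΔF|)), which makes this model the independent
  oracle for the hopping algorithm: the gap-based hopping formula must
  reproduce it without ever seeing the diabatic coupling.
* **`model_avoided_crossing()`** — a single avoided crossing with a
  localized Gaussian coupling, for dynamics with an asymptotically flat
  landscape.
* **`model_lvc3()`** — two coordinates (a tuning mode x1 and a coupling
  mode x2), three states.  The diabats are displaced wells
  V_kk = k/2·(x1²+x2²) + q/4·(x1⁴+x2⁴) + κ_k·x1 + ε_k with linear
  couplings λ·x2 between every state pair.  The defaults
  (k = 0.05, q = 0.008, ε = (0, 0.08, 0.12), κ = (0, −0.06, −0.12),
  λ = 0.03, masses 2000) put the S2/S1 diabatic crossing at
  x1 = 2/3 bohr and the S1/S0 crossing at x1 = 4/3 bohr, both downhill
  from the Franck–Condon point, so a wavepacket excited to S2 cascades
  through both seams within a few tens of fs — the structure of a
  pericyclic photoreaction at desk scale.  True conical intersections
  (gap → 0) sit on the x2 = 0 line.

Two design choices in the three-state model deserve justification:

* **Quartic anharmonicity.** A strictly harmonic model with a common
  force constant is isochronous: every trajectory returns to the seam
  region in phase, and the ensemble shows perfectly coherent
  recurrences forever.  No multidimensional molecule behaves this way —
  energy disperses into the remaining modes and the ensemble dephases.
  The small state-independent quartic term restores this dephasing
  (the vibrational period becomes amplitude-dependent) without moving
  any diabatic crossing, because it shifts all diagonal entries
  equally.
* **All pairs coupled.** With V13 = 0 the crossing of diabats 1 and 3
  would be an exact intersection along an entire line transverse to the
  dynamics, and every vibrational return would flip the adiabatic
  character with probability one, producing unphysical population
  sloshing.  Coupling every adjacent and non-adjacent pair through the
  same λ·x2 term makes all passages partially adiabatic.

## Wigner sampling

Initial conditions are drawn from the ground-vibrational-state Wigner
distribution of a harmonic normal-mode specification: per mode,
position and momentum are independent Gaussians with Var(q) = ħ/(2ω)
and Var(p) = ħω/2 in mass-weighted coordinates.  Temperature is fixed
at 0 K; thermal (finite-temperature) sampling is out of scope.  The
sampler is state-agnostic — the caller chooses the initial electronic
state, and the shipped workflows launch on the topmost state of the
cascade.  An excitation-window filter keeps samples whose vertical
gap lies in a caller-chosen interval; the window itself is a required
input because no default width is universal.

## Propagation and hopping

Nuclei follow velocity Verlet on the active adiabatic surface.  The
hopping scheme is the coupling-free Landau–Zener–Belyaev–Lebedev
formula: along the trajectory the gap Z(t) between the active state and
each adjacent state is monitored, and at a strict local minimum of Z a
hop is attempted with

P = exp( −(π/2ħ) · sqrt( Z³ / Z̈ ) ),

where Z̈ is the second time derivative of the gap, estimated by the
three-point central difference (Z_{i−1} − 2Z_i + Z_{i+1})/dt².  Exact
degeneracy (Z = 0) gives P = 1.  Numerical choices, all deliberate:

* **Strict minima only.** Plateaus never trigger hops; this avoids
  repeated firing on flat gaps.  The minimum is used as detected on the
  time grid — no interpolation between steps — so dt must resolve the
  gap minimum (the time-step-halving test checks exactly this).
* **One attempt per detected minimum.** If two state pairs minimize on
  the same step, the smaller gap goes first and the other pair is
  dropped for that step.
* **Energy bookkeeping.** An accepted hop rescales all velocities
  uniformly by sqrt(1 + ΔE/KE), conserving total energy to machine
  precision.  Upward hops are vetoed (recorded as frustrated) when the
  available kinetic energy cannot pay the gap.  With the *reduced
  kinetic-energy reservoir* flag the energy deemed available is the
  total kinetic energy divided by the number of internal degrees of
  freedom — a deliberately isolated predicate, since the convention
  varies between implementations.
* **Step-indexed hop stream.** The uniform variate consumed by a hop
  attempt at step i is drawn up front as the i-th element of a
  pregenerated per-trajectory stream.  For a single run this is
  statistically identical to drawing on demand; for *paired* runs of
  the same initial conditions on two nearby potentials it implements
  common random numbers: a spurious extra gap minimum in one run no
  longer desynchronizes every later decision.  Paired comparisons (the
  gradient-free versus gradient-trained check below) owe most of their
  power to this.
* **Terminations.** A trajectory ends at t_max, when the potential's
  per-state ensemble uncertainty exceeds a threshold (default
  0.03 hartree), when a caller-supplied distortion predicate fires
  (default for molecular coordinates: any pairwise distance outside
  0.5–5× its initial value), or on numeric failure — always returned as
  a termination reason, never thrown mid-batch.

## The surrogate

A plain feed-forward network (tanh hidden layers, default 2×48; one
linear output head per state) maps the coordinates, standardized by the
training set, plus a one-hot fidelity descriptor to the per-state
energies.  Forces are the exact analytic derivatives of the network
output (forward-mode differentiation), never finite differences —
this is the mechanism under test, so the derivative code is verified
against central differences in the suite.

The training loss is

L = ω_E·mean‖E − E_ref‖² + ω_gap·mean‖g − g_ref‖² + ω_F·mean‖∇E − ∇E_ref‖²,

with g the adjacent-state gaps E_{k+1} − E_k and the force term running
only over records that carry reference gradients.  Defaults
ω = (1, 1, 0.1) for energies, gaps and gradients.  The gap term is
defined over adjacent pairs; nothing in the protocol pins down whether
all pairs should enter, and adjacent pairs are the ones that drive
hopping.  Optimization is Adam under a reduce-on-plateau learning-rate
schedule (initial 0.001, factor 0.5, patience 50 epochs, stop below
1e−5), with a 10% random validation split; the plateau criterion uses
the full composite loss, and the returned parameters are those with the
best validation loss.  A hard `max_epochs` cap exists as a safety
valve.  All of this is reproducible from the schedule seed.

Ensembles of surrogates share their initial weights and differ only in
the stochastic training streams; predictions average the members, and
the per-state standard deviation across members is the uncertainty fed
to the propagation threshold above.

## Statistics

* Populations are trajectory fractions per state on a time grid, with
  normal-approximation binomial half-widths z·sqrt(p(1−p)/n)
  (z = 1.959964 at 95%).  Early-terminated trajectories either hold
  their last state or are dropped — both modes exist because completion
  rates below 100% are the norm, and the two conventions bracket the
  truth.
* Bootstrap standard errors resample trajectories with replacement
  (optionally at a reduced fraction per replicate) and apply to the
  population matrix or to any caller-supplied reducer.  The
  fit-covariance standard errors of the nonlinear decay fits
  *undercover badly* (empirical-CDF points are strongly autocorrelated,
  so the iid assumption of least squares is violated); the bootstrap
  over trajectories is therefore the estimator used wherever a
  timescale uncertainty is quoted.
* Timescale fits: P(t) = 1 − exp(−t/τ) (plain) or
  P(t) = 1 − exp(−(t − t0)/τ) for t ≥ t0 and 0 before (delayed), by
  Levenberg–Marquardt least squares.  Initial guesses: τ from the time
  to reach 1 − 1/e of the final plateau, t0 from the first time the
  population exceeds 0.02.
* Product classifiers are strict threshold rules exactly as a
  fingerprint would be printed — a bond distance strictly above a
  threshold, an absolute dihedral strictly below one — with ties going
  to the non-reactive class.  Quantum yields Φ = N_reactive/N_traj
  carry binomial half-widths; trajectories flagged distorted or
  uncertain are excluded from classification.
* Hop tables collect accepted hops of a state pair with arbitrary
  geometric measures and the owning trajectory's product label;
  branching ratios count products among hops within a window (default
  ±20°) of the intersection dihedral and report the out-of-window
  fraction separately.

## Minimum-energy conical intersections

`optimize_meci()` minimizes the penalty objective
F(x) = (E_I + E_J)/2 + σ·ΔE²/(ΔE + α) using only energies and
gradients of the two states — no nonadiabatic coupling vectors, which
do not exist in the gradient-free setting.  σ starts at 3.5 and doubles
each outer cycle (α = 0.02 hartree) until the gap and the objective
gradient norm meet their tolerances; the inner minimizer is L-BFGS on
Cartesian coordinates.  Cycle-level monotonicity is asserted (an inner
result that increased the objective is discarded), and exceeding the
cycle budget returns `converged = FALSE` with the best geometry rather
than raising.

## The headline check, and what it does and does not show

`gradient_free_benchmark()` packages the central comparison: on the
three-state model, two surrogate ensembles (4 members, 2×48 tanh
layers) are trained on the same 500 geometries — 30% spread over the
dynamically accessible box, 70% concentrated around the crossing seams,
the way an actively sampled training set concentrates where hops
happen.  Both see an auxiliary "lower level of theory" (the same model
with slightly shifted parameters) with energies *and* gradients; they
differ only in whether the target-level records carry gradients.  Each
drives 500 trajectories (0.1 fs steps, 60 fs) from identical Wigner
initial conditions with identical hop streams, and the population
curves are compared on a 0.5 fs grid: the protocol claim holds when the
two curves stay inside each other's 95% confidence bands everywhere,
i.e. max |ΔP| / (ΔP₉₅ᴬ + ΔP₉₅ᴮ) ≤ 1.  Problem sizes (500 training
geometries, 500 trajectories, 4 members) are the package's chosen
desk-scale study conditions.

What passing shows: with auxiliary-fidelity gradients anchoring the
shape of the surfaces, removing the target-level gradients does not
change the ensemble dynamics by more than the trajectory-count noise,
on smooth low-dimensional surfaces with genuine conical intersections,
recurrences and frustrated hops.  What it does not show: anything about
high-dimensional molecular potential-energy surfaces, real
electronic-structure label noise, or geometries far outside the
sampled box — the analytic models have no basis-set artifacts, no
state-ordering noise in the labels, and only two nuclear coordinates.
Without the auxiliary gradients, energy-only training at this training
set size visibly rounds the gap cusps near the seams and slows the
first cascade; the auxiliary level is not decoration but a load-bearing
part of the protocol.

## Known limitations

* The one-hot fidelity mechanism supports any number of levels, but
  nothing transfers *between* fidelities beyond the shared hidden
  layers; there is no explicit delta-learning head.
* The LZBL scheme has no decoherence correction and no electronic
  amplitudes; it is a hopping-probability scheme, and disagreements
  with fewest-switches dynamics at strong coupling are expected.
* The gap-minimum detector works on the integration grid; a dt too
  coarse to resolve the gap minimum biases hopping probabilities.
* The Wigner sampler is harmonic and 0 K; the anharmonic corrections of
  the quartic model term are ignored at sampling time (they shift the
  true ground-state width by well under the 5% tolerance the tests
  allow).
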