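# gfnamd — gradient-free machine-learned nonadiabatic molecular dynamics

Surface-hopping nonadiabatic dynamics normally needs analytic forces
from the underlying electronic-structure method, which excludes many of
the most accurate multireference methods: their gradients exist only by
numerical differentiation, at a cost proportional to the number of
degrees of freedom.  `gfnamd` implements, at desk scale, the protocol
that removes this bottleneck: fit a differentiable multi-state
surrogate potential to **energies only** and obtain the forces by
analytic differentiation of the fitted model.  The package is for
computational photochemists and method developers who want to study,
test or teach this protocol end to end with every stage observable and
every claim testable against built-in analytic ground truth.

The package provides:

* **Analytic diabatic model potentials** standing in for the reference
  electronic structure: a 1D linear crossing (with the exact
  Landau–Zener transition probability as oracle), a single avoided
  crossing, and a 2-coordinate, 3-state vibronic model with true
  conical intersections and an S2 → S1 → S0 cascade.
* **A multi-fidelity feed-forward surrogate** (one output head per
  state, one-hot fidelity descriptor on the input) trained by Adam
  under a reduce-on-plateau schedule on the composite loss
  `L = ω_E·L_E + ω_gap·L_gap + ω_F·L_F` (defaults 1, 1, 0.1); the force
  term only ever sees records that carry reference gradients.  Forces
  are exact analytic derivatives of the network.  Ensembles of
  surrogates give mean predictions plus a per-state uncertainty used to
  terminate unreliable trajectories (default threshold 0.03 hartree).
* **Wigner sampling** of harmonic ground-state initial conditions, with
  excitation-window filtering.
* **Velocity-Verlet propagation with Landau–Zener–Belyaev–Lebedev
  hopping**: at strict local minima of the adiabatic gap Z, a hop is
  attempted with `P = exp(−(π/2ħ)·sqrt(Z³/Z̈))`, Z̈ by three-point
  central difference; upward hops are vetoed when kinetic energy cannot
  pay the gap, accepted hops rescale velocities to conserve total
  energy exactly.
* **The statistics layer**: population curves with binomial 95%
  confidence bands `ΔP = z·sqrt(P(1−P)/n)`, bootstrap standard errors,
  plain and delayed exponential timescale fits
  `P(t) = 1 − exp(−(t−t0)/τ)`, quantum yields `Φ = N_reactive/N_traj`,
  threshold product classifiers, hop-geometry tables, branching ratios
  near a conical intersection, linearly interpolated paths.
* **Penalty-function MECI optimization**
  `F(x) = (E_I+E_J)/2 + σ·ΔE²/(ΔE+α)` using energies and gradients
  only — workable on gradient-free surrogates by construction.
* Plain-text formats (extended XYZ, labeled datasets, checkpoints) and
  a `gfnamd` command-line entry point (`exec/gfnamd`) for the
  sample → propagate → analyze → meci pipeline.

## Worked example

Propagate 500 hopping trajectories through the linear crossing and
compare the ensemble transition fraction with the closed-form
Landau–Zener probability, then locate the minimum-energy crossing
point:

```r
library(gfnamd)
model <- model_linear_crossing()           # F = 0.01, H12 = 0.005, m = 2000
ini <- list(coords = -2, velocities = 0.011, state = 1)

ens <- run_ensemble(model, replicate(500, ini, simplify = FALSE),
                    propagation_settings(dt_fs = 0.1, t_max_fs = 12, seed = 1),
                    base_seed = 100)
pop <- populations(ens)
print(pop)
#> Population curve: 2 states, 121 grid points, 500 trajectories
#>   final populations (t = 12.0 fs): S0=0.556 S1=0.444

e_lower <- function(x) -sqrt((0.01 * x)^2 + 0.005^2)
v_cross <- sqrt(2 * (0.5 * 2000 * 0.011^2 + e_lower(-2) - e_lower(0)) / 2000)
landau_zener_reference(0.005, 0.02, v_cross)
#> [1] 0.4653012

meci <- optimize_meci(model, x0 = 1.5, states = c(1, 2),
                      settings = penalty_settings(gap_tol = 0.0101,
                                                  grad_tol = 1e-5))
print(meci)
#> MECI optimization (states 1/2): converged after 1 cycle(s)
#>   geometry (bohr): -0.000000
#>   gap: 1.000e-02 hartree; E = -0.005000 0.005000
```

The ensemble ends with 44.4 ± 4.4% of trajectories on the upper
adiabat; the analytic single-passage probability is 46.5%, inside the
binomial confidence interval.  The seam optimizer converges to the
crossing at x = 0, where the gap equals twice the diabatic coupling.

The headline comparison — a gradient-free versus a gradient-trained
surrogate ensemble driving 500 trajectories each on the three-state
cascade model — is packaged as `gradient_free_benchmark()`; see the
methods vignette (`vignettes/gradient-free-namd.Rmd`) for what it
computes and why.

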