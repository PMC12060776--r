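---
title: "Field-embedded machine-learned surface hopping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-embedded machine-learned surface hopping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fieldhop)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, the design choices
made where the design was genuinely open, and what the built-in synthetic
systems do and do not establish about real simulations.

## 1. Electrostatic embedding and field-consistent forces

A chromophore ("ML region") in a classical point-charge environment ("MM
region") couples to the environment in two ways: short-range
Lennard-Jones interactions handled classically, and the Coulomb
interaction, which enters the chromophore's electronic Hamiltonian as an
external potential.  The package represents the environment to the
electronic problem solely through the electric field at the chromophore
atoms,

$$\varepsilon_i \;=\; \sum_{j}^{N_{\rm MM}} q_j
  \frac{\mathbf R_i - \mathbf R_j}{|\mathbf R_i - \mathbf R_j|^3},$$

in atomic units, with the sum running over *all* charge sites — no
cutoff.  The package works with finite charge droplets precisely so that
this cutoff-free sum is exact; there is no Ewald or periodic variant.

Because the embedded state energies are functions
$E_k(\{\mathbf R^{\rm ML}\}, \{\varepsilon_i\})$ and the field depends on
every nuclear position, consistent forces need the chain rule through the
field:

$$\mathbf F_{\rm ML} = -\frac{\partial E}{\partial \mathbf R_{\rm ML}}
  - \sum_i \frac{\partial E}{\partial \varepsilon_i}\cdot
    \frac{\partial \varepsilon_i}{\partial \mathbf R_{\rm ML}},
 \qquad
 \mathbf F_{\rm MM} = -\sum_i
    \frac{\partial E}{\partial \varepsilon_i}\cdot
    \frac{\partial \varepsilon_i}{\partial \mathbf R_{\rm MM}}.$$

The field Jacobians are the closed-form dipole tensors
$(q_j/r^3)(\mathbb 1 - 3\hat r\hat r^{\mathsf T})$; among ML atoms,
$\varepsilon_i$ depends only on $\mathbf R_i$.  Two identities pin the
implementation down and are enforced by tests: the field is minus the
gradient of the charge cloud's electrostatic potential, and the
field-mediated forces over ML plus MM atoms sum to zero (the field is
translation invariant, so the embedding exchanges momentum but never
creates it).

Units are a single table in `fh_const`: positions in Å, energies in eV,
time in fs, masses in amu, charges in e, fields in atomic units; error
reports convert to kcal/mol and kcal/(mol·Å).  Fields are kept in atomic
units end to end so training labels and dynamics can never drift apart in
unit conventions.  Frames with an ML–MM contact below $10^{-6}$ Å are
rejected at validation rather than by softening the Coulomb kernel:
softening would silently corrupt the finite-difference exactness tests.

## 2. The analytic oracle

Reference electronic structure is replaced by the smallest analytic model
with all the structure the machinery needs: avoided crossings, field
response, exact gradients and exact nonadiabatic couplings.  The diabatic
Hamiltonian has

- diagonal entries
  $V_k(\mathbf R) = \Delta_k + \tfrac12\sum_{i<j}\kappa^k_{ij}
   (r_{ij} - r^{0,k}_{ij})^2 - \sum_i \boldsymbol\mu_{k,i}\cdot
   \boldsymbol\varepsilon_i$ — a per-state harmonic *bond network* over
   all interatomic distances, with equilibrium distances taken from the
   state's minimum geometry, plus a vertical shift and a linear
   dipole–field coupling;
- constant (optionally Gaussian-of-a-bond-length) off-diagonal couplings.

The bond-network form matters: it makes the oracle exactly invariant
under rigid translations and rotations, with zero net force and torque.
An earlier formulation with harmonic wells in Cartesian displacements
pins the molecular *orientation* to the lab frame, which no
rotation-invariant regressor can represent — the learning problem becomes
ill-posed by construction.  The dipole-coupling vectors
$\boldsymbol\mu_{k,i}$ remain fixed lab-frame parameters; under the
package's covariance contract a rigid rotation is applied to positions,
bath, *and* these dipole parameters together.

Adiabatic states come from exact diagonalisation, sorted by energy, with
eigenvector signs fixed to maximise overlap with the previous step's
eigenvectors.  This continuity contract is load-bearing: without it,
arbitrary sign flips between steps decorrelate the electronic coherences
from the couplings and corrupt hopping statistics (single-passage
transfer on the two-state model moves from the Landau–Zener value to
essentially random).  Forces use the Hellmann–Feynman rule,
$\langle k|\partial H/\partial\mathbf R|k\rangle$ at fixed field plus the
field chain term with
$\partial E_k/\partial\varepsilon_i =
 -\sum_a U_{ak}^2\,\boldsymbol\mu_{a,i}$; couplings are
$\mathbf d_{kl} = \langle k|\partial H/\partial\mathbf R|l\rangle /
 (E_l - E_k)$, including the field-mediated position dependence.  All of
these match central finite differences of the adiabatic energies to
relative $10^{-6}$ or better (tested on random frames).

Two systems ship with the package, their parameters fixed constructor
defaults rather than tuning knobs:

- `default_oracle_spec()` — a planar nine-atom C4H4O ring with five
  states.  Excited minima stretch the two carbon–oxygen bonds (a
  ring-opening coordinate) with softened force constants; vertical shifts
  (0, 6.2, 6.6, 7.4, 7.8 eV) put the second excited state inside a
  6–7 eV excitation window, which together with a bright transition
  dipole on that state reproduces the "excite the bright state in a
  window" initial-condition protocol.  Excitation windows for this oracle
  must be chosen where *its* states absorb; the windows are arguments,
  not constants.
- `two_state_spec()` — a hydrogen diatomic with two bond-length diabats
  (1.2 and 2.0 Å, 8 eV/Å² per atom) crossing at 1.6 Å with a 0.15 eV
  constant coupling.  Released from the short-bond minimum on the upper
  adiabat, it passes the crossing in the mixed Landau–Zener regime
  (single-passage transfer ≈ 0.88 analytically), which is where coupling
  schemes can be meaningfully compared.

The charge bath is a finite droplet: mobile sites with Lennard-Jones
interactions to the ML atoms *and among themselves* plus Coulomb forces
(bare point charges with no short-range repulsion of their own collapse
onto each other).  Defaults are water-like: ±0.4 e alternating charges,
σ = 3.166 Å, ε = 0.0103 eV, 18 amu sites, an 18 Å droplet.

### Initial-condition sampling

Ground-state initial conditions follow the standard molecular-dynamics
protocol in miniature: the freshly placed bath is relaxed by steepest
descent (removing the association energy a random placement would
otherwise dump into the dynamics), then the full system runs BAOAB
Langevin dynamics on the lowest adiabatic surface with friction in
ps⁻¹ (default 2), and snapshots are recorded at fixed strides.  At each
snapshot boundary all velocities are redrawn from the Maxwell–Boltzmann
distribution (Andersen-style resampling).  This guarantees that recorded
frames carry exactly thermal velocities and decorrelates successive
snapshots even when the strongly associating charge droplet keeps
releasing energy more slowly than the weak friction can remove it — the
desk-scale substitute for the nanosecond equilibrations a real solvent
box would get.  Sampling is deterministic for a fixed seed, and the
ensemble kinetic temperature matches the target to a few percent.

## 3. The field-aware regressor

The regressor predicts all adiabatic state energies jointly from ML
coordinates and per-atom fields.  Each atom is featurised by smooth
rotation- and translation-invariant descriptors:

- radial Gaussians of neighbour distances (50 equidistant centres on
  `[0, cutoff]` by default, cosine cutoff at 10 Å), resolved by the
  neighbour's element;
- projections of the atom's field vector onto its interatomic unit
  vectors, in the same radial basis (these are linear in the field, the
  natural symmetry-adapted representation of a dipole coupling);
- the squared field norm.

A per-element linear multi-state readout maps descriptors to energies.
Everything downstream — energy gradients with respect to positions at
fixed field, and with respect to the field — is analytic and exact, so the
losses, the dynamics forces, and the model are consistent by
construction.  Linear readouts over fixed invariant descriptors are an
established class of interatomic potentials; the package deliberately
prefers exact gradients and deterministic training over a deep
message-passing stack, and the acceptance surface is the analytic oracle,
not any particular network architecture.  `model_config()` accepts and
records `n_interactions`, `feature_width` and `readout_widths` for
completeness, but the linear readout does not consume them.

Training minimises either the standard loss — energy mean squared error
plus `w_F` times the force mean squared error, with the predicted force
being the plain negative direct gradient — or the *augmented* loss, whose
predicted force includes the field chain term, i.e. exactly the force
used in dynamics.  The declared averaging convention (the loss examples
in the tests depend on it) is: mean over frames, over states, and over
all `3 N_ML` force components.  The optimiser is Adam (moments 0.9/0.999,
batch size 10, default starting step 1e-5) with a plateau scheduler that
multiplies the step by 0.8 after 20 stale validation epochs, stops below
1e-6, caps at 5000 epochs, and returns the best-validation checkpoint.
The validation metric is the same loss being trained; gradient clipping
is off.  Training is deterministic for a fixed seed and thread count; no
cross-seed equality of trained models is promised anywhere — seed-level
variability of the resulting dynamics is expected and must not be
asserted away.

On zero-field data the augmented loss reduces exactly to the standard
one.  On field-coupled oracle data, a model trained with the augmented
loss achieves lower test error on the total embedded forces than the
same-seed model trained with the standard loss: the standard loss asks
the direct gradient alone to reproduce a force that provably contains a
field-mediated part, an irreducible bias the augmented loss removes.

## 4. Surface hopping

Nuclei propagate by velocity Verlet (default 0.5 fs) on the active
adiabatic surface; bath sites feel the field-mediated force plus their
classical terms.  Electronic coefficients follow
$i\hbar\,\dot c = (\mathrm{diag}(E) - i\hbar T)\,c$ integrated with
exponential-midpoint substeps (default 0.025 fs) on linearly interpolated
energies with the coupling matrix held fixed across the nuclear step;
each substep propagator is the exact exponential of an anti-Hermitian
generator, so the norm is conserved to rounding (the engine enforces
drift below $10^{-6}$ per step and typically sees $10^{-13}$).

Couplings come from one of two schemes:

- `exact_nac` — $T_{kl} = \mathbf v_{\rm ML}\cdot\mathbf d_{kl}$ from the
  oracle's analytic coupling vectors (reference dynamics only);
- `curvature` — a surrogate usable with learned potentials because it
  needs energies only:
  $\sigma_{kl} = \tfrac12\sqrt{\max(0, \ddot g_{kl}/g_{kl})}$ with
  $g_{kl}$ the gap, its second time derivative from the exact three-point
  stencil $(g(t-\Delta t) - 2g(t) + g(t+\Delta t))/\Delta t^2$, the gap
  taken at the central point, and a clamp to zero at negative arguments.
  The first two nuclear steps of a trajectory have no complete stencil
  and use zero coupling (this affects 1 fs of dynamics).

Hops follow the fewest-switches rule: the probability of leaving the
active state $a$ for $m$ is the clipped population outflow
$\max(0,\, 2 T_{am}\,\mathrm{Re}(c_a^* c_m)\,\Delta t / |c_a|^2)$, and a
single uniform random number selects the channel by cumulative
intervals.  Accepted hops rescale the ML-atom velocities by a single
uniform factor so the ML kinetic energy absorbs exactly the potential
energy change (bath velocities untouched — the quoted protocol rescales
the quantum-region particles only; rescaling the bath too would be the
other defensible reading).  Uphill hops the kinetic energy cannot pay are
frustrated: recorded, but the state and velocities are unchanged.  There
is no decoherence correction, matching the reference protocol; the
configuration object is the natural extension point if one is wanted.

Two special rules mirror the reference protocol for regions the
underlying electronic structure cannot describe: whenever the active
state is the first excited state and its gap to the ground state is below
0.1 eV, a hop to the ground state is *forced* (same rescaling rules — it
is downhill, so always accepted; the alternative always-accept reading
would behave identically); and once a trajectory reaches the ground
state, upward channels are disabled.  Electronic coefficients are left
untouched by forced hops.  Per nuclear step the order is: electronic
substeps, stochastic hop attempt, forced-gap check last — so the 0.1 eV
rule can never be preempted.  Trajectories whose total energy drifts
beyond a threshold (default 5 eV) are truncated and flagged rather than
discarded, and the population denominator downstream counts only alive
trajectories.

On the curvature scheme's fidelity: on the two-state diatomic the
surrogate transfers *more* population per passage than the exact
couplings (0.90 versus 0.46 on the first pass under the default
parameters), but ensembles converge to the same final ground-state
populations within a few percent after a handful of passages — the
premise under which the scheme is used as a drop-in for learned
potentials, and exactly what the scheme-equivalence acceptance check
measures (500 trajectories per scheme, final populations within 0.1).

## 5. Evaluation toolkit

**Splits.** Time subsampling (every stride-th frame of each trajectory,
counting from zero) is applied before assignment.  "Split by trajectory"
allocates whole trajectories — for 46 of them the default fractions give
37/5/4 — avoiding the temporal leakage that makes random-split test
errors optimistic; "random" pools retained frames 80:10:10.  Assignments
are disjoint, exhaustive over retained frames, and seed-deterministic.

**Gap-weighted errors.** Accuracy near intersection seams is what
hopping feeds on, so plain test errors are complemented by a weighted
RMSE in which configuration $i$ in state $j$ carries weight
$w_i^j = 1/(\text{min adjacent gap} + \delta)$, $\delta = 10^{-3}$ eV,
normalised so that uniform gaps reproduce the plain RMSE exactly.  The
inverse-gap form satisfies the qualitative contract (small gaps dominate)
while remaining exactly reducible; other decaying weights would serve the
same purpose.

**Kinetics.** Active-state populations on the nuclear time grid feed a
two-constant sequential model
$P_2 = e^{-t/\tau_{21}}$,
$P_1 = \tfrac{\tau_{10}}{\tau_{10}-\tau_{21}}
 (e^{-t/\tau_{10}} - e^{-t/\tau_{21}})$ (with the analytic limit at equal
constants, implemented in a form bounded for all parameter values),
$P_0 = 1 - P_1 - P_2$, fitted jointly over the three curves by
least squares on log time constants.  Uncertainties resample
*trajectories* (the independent units) with replacement — 200 bootstrap
replicates, percentile intervals.  On noiseless curves with 17 fs and
65 fs constants the fit recovers both to better than 0.1 fs; on
stochastic 66-trajectory ensembles the joint bootstrap coverage of both
constants sits at the expected ~0.9 (two 95% intervals jointly), which
the calibration check verifies over 50 replicates.

**Geometry analysis.** Hopping geometries are Kabsch-aligned (SVD with
the determinant sign correction), featurised by the Coulomb matrix
(off-diagonal $Z_iZ_j/r_{ij}$ with distances in bohr, diagonal
$0.5\,Z^{2.4}$, fixed atom order — the chromophore's atom identity is
constant, so no row-norm sorting), and decomposed by PCA computed on the
reference set only (centred, not scaled); other sets are projected with
the stored transform, never refitted, so reference and model hopping
seams share one coordinate system.  The bond projection
(max of two chosen bond lengths) is the natural 1D coordinate of a
symmetric ring opening.

**Spectra.** Transitions are convolved with a Gaussian of 0.2 eV full
width at half maximum; the integrated intensity equals the summed
oscillator strengths, with strengths from the oracle's transition dipoles
via $f = \tfrac23\,\Delta E\,|\mu|^2$ in atomic units.

## 6. Problem sizes, numerical choices, limitations

The test suite and the acceptance script use deliberately small
instances, chosen as the smallest sizes at which each property is
statistically decidable: 20 random frames for finite-difference
exactness; 300 fs microcanonical runs; ensembles of 100–500 trajectories
for hop audits and scheme comparisons; training sets of 200–500 frames
with 10–16 radial basis functions; 50 replicates of 66 trajectories for
bootstrap calibration.  One global seed fans out to per-stage seeds
through a fixed counter scheme (`fh_seed`), so every artifact is
reproducible from one integer.

What the synthetic systems do *not* establish: the oracle's surfaces are
harmonic bond networks with constant couplings — far smoother than real
excited-state surfaces, with no bond breaking, no conical-intersection
topology beyond avoided crossings, no wavefunction character changes, and
lab-frame dipole parameters instead of a charge distribution that
responds to geometry.  The bath is a structureless charge droplet: no
molecular solvent, no hydrogen bonding, no constrained bonds, no periodic
boundaries.  Passing tests therefore demonstrate that the *machinery* —
embedding algebra, integrators, hopping rules, losses, statistics — is
correct and internally consistent, not that a model trained this way will
be accurate for any particular real chromophore.  Learned-potential
trajectories remain vulnerable to extrapolation blow-up when they leave
the trained region (the engine detects and flags this); training data
must cover the configurations the dynamics will visit, which is why the
pipeline trains on excited-state reference trajectories rather than
ground-state thermal frames.

Numerical details fixed by design: eigensolves symmetrise their input and
break ties by energy sort plus previous-step sign continuity; degenerate
states (gap below $10^{-8}$ eV) make coupling vectors undefined and raise
errors rather than returning garbage; near-degenerate frames (gap below
$10^{-10}$ eV) are flagged in their labels; text artifacts serialise at
fixed precision so regression comparisons are byte-stable; archives are
runtime R serialisations with a schema version, while all shipped
fixtures are plain text.
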