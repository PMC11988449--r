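---
title: "Discovering cryptic pockets with crypticsite: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cryptic pockets with crypticsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticsite)
```

# The problem

Allosteric modulators sometimes act through *cryptic* pockets: cavities
that are closed in every experimental structure and open only through
slow conformational fluctuations. Finding such a pocket computationally
requires (i) sampling the rare opening transition without biasing the
thermodynamics, (ii) ranking docked ligand poses by both their docking
score *and* the equilibrium probability of the receptor conformation
that hosts them, and (iii) discarding candidate sites that a ligand
could never actually reach from solvent. `crypticsite` implements this
pipeline for pentameric ligand-gated ion channel–like systems, with a
synthetic-data module standing in for the molecular-dynamics and docking
engines so every stage is exercised by fast, deterministic tests.

This vignette records the models, the tunable parameters and the design
decisions that were genuinely open, in the package's own words.

# The synthetic system

## Toy dynamics

`toy_potential()` defines
$$U(x) = \tfrac12 k_c\lVert x\rVert^2 - \sum_j A_j
  \exp\!\big(-\lVert x - c_j\rVert^2 / 2w_j^2\big),$$
a sum of inverted Gaussian wells on a quadratic confinement — bounded
below, with an integrable Boltzmann weight, and with analytic forces.
`simulate_brownian()` integrates overdamped Langevin dynamics
(Euler–Maruyama, unit friction) with noise drawn from R's RNG, so a seed
reproduces a trajectory bit for bit. A guard refuses timesteps whose
one-step noise displacement exceeds 0.2× the minimum well separation.

The default landscape (`three_well_potential()`) has three metastable
basins along one slow coordinate — closed, intermediate and open-pocket —
mirroring the three-state topology seen in the full-scale free-energy
surfaces. Defaults: wells at x = 0, 2, 4 (reduced length units), depths
9, 8, 9 kT, width 0.55, confinement 0.05 kT per unit², kT = 1, timestep
0.01. These give inter-well barriers near 6 kT, so a single 400-step
simulation rarely crosses — pocket opening is genuinely rare at the
swarm length the controller uses, which is the property the adaptive
sampler needs to demonstrate an advantage. The basin-quadrature tests
use shallower fixtures so equilibrium is reachable in 10^6 steps.

`toy_embed()` maps toy coordinates onto a pentamer bead model: five
subunits on a ring, each with wall beads fixed and loop beads displaced
outward by `base_distance + x` (the fast coordinate becomes a small
tangential displacement). Loop–wall nearest-atom distances therefore
track the slow coordinate the way omega-loop-to-beta-strand distances
report pocket opening, and the analytic featurizer
(`toy_featurize_fn()`) is tested to agree with full bead-model
featurization to 1e-10.

## Sphere receptors with planted ground truth

`build_sphere_receptor()` builds one-sphere-per-atom receptors whose
accessibility is known by construction: a densely packed spherical shell
(Fibonacci lattice, spacing 2.2 Å, carbon vdW radius 1.7 Å — neighbour
gaps are negative, i.e. sealed) encloses each cavity, and an optional
tunnel is drilled and lined with staggered atom rings whose inner
surface sits exactly `channel_radius` from the tunnel axis. The planted
bottleneck is therefore `channel_radius` itself (0 for a sealed cavity),
and the ground-truth JSON the builder emits is what the accessibility
module must recover without peeking. The demo receptor plants a 3.0 Å
open site and a 1.2 Å buried site, matching the two thresholds the
open/buried decision rule straddles.

## Surrogate scores, ligand traces and dose–response data

Docking is emulated by `surrogate_scores()`:
$g_i = g_0 - \text{slope}\cdot\text{openness}_i + \epsilon_i$, Gaussian
noise, seeded — one best pose per conformation, with more-open
conformations scoring better in expectation. Gaussian noise is the
simplest calibrated choice and its SD is exposed in the configuration.
Ligand stability trajectories come from `simulate_ligand_trace()`: a
bounded Ornstein–Uhlenbeck walk (stationary displacement SD 1.5 Å) for a
stable pose, an outward drift escaping far beyond 15 Å for an unstable
one. `synth_dose_response()` evaluates the Hill equation exactly and
adds seeded Gaussian noise.

**What the synthetic data do not emulate:** force-field physics,
solvent, side-chain rearrangement, docking-pose geometry beyond a point
cloud, or correlated electrophysiology artifacts. Passing tests
demonstrate that the *pipeline logic* — reward-driven reseeding, MSM
estimation, reweighting arithmetic, clustering, filter semantics,
tunnel search — is correct on systems with known answers; they do not
validate force fields or docking scores on real proteins.

# Adaptive sampling

The controller (`run_fast()`) reseeds each generation from the full set
of stored frames, ranked by $r = \tilde\phi + \alpha\tilde\psi$ with
min–max normalization over the discovered set, default $\alpha = 1$, and
deterministic ties (earlier discovery wins). The directed metric is the
mean loop–wall distance; the exploration metric is
$\psi = 1/(1+n)$ with $n$ the neighbours within an RMSD-type radius
(default 0.4 in toy coordinates, configurable — the full-scale
equivalent would be of order 1.5 Å over the extracellular-domain
selection). The functional form of the reward and the normalization were
open choices: the simplest published FAST scheme is used, with
$\alpha$ exposed rather than asserted. Candidate seeds are every stored
frame (stride 10 by default), not trajectory endpoints, because the
method draws from *all previously discovered conformations*.

Individual trajectories are never biased, so the pooled data feed the
MSM estimators unchanged. The efficiency experiment pairs the reward
policy against uniform-random reseeding at identical budgets and seeds;
under the default landscape the reward policy reaches the open basin
first in roughly three quarters of paired repeats (18 of 20 at the
fixed seed set the acceptance suite uses), typically within 2–7k engine
steps versus frequent non-arrival for the random baseline.

# Markov state modelling

Discretization uses k-means++ seeding with 10 restarts and Lloyd
iterations, keeping the lowest inertia — determinism and robustness over
cleverness. Transition counting is sliding-window (every (t, t+τ) pair),
which maximizes data use; strided counting would be less correlated but
wastes data, and the choice is recorded here because either is
defensible. Counts are trimmed to the largest strongly connected
component before estimation — π does not exist otherwise.

The reversible maximum-likelihood transition matrix is the standard
self-consistent fixed point on the symmetric flux matrix, iterated to
`max |Δx| < 1e-10` (capped at 10^6 sweeps, with an error rather than a
silent result on non-convergence). Two-state chains reproduce
row-normalized counts exactly; random four-state problems agree with a
direct constrained optimizer to 1e-6 in log-likelihood and satisfy
detailed balance to 1e-8. Eigen-decompositions of the reversible kernel
go through the π-symmetrized similar matrix for numerical symmetry.
Implied timescales $t_k = -\tau/\ln\lambda_k$ flag non-positive
eigenvalues as undefined instead of propagating NaN.

tICA symmetrizes the covariance estimates over forward and reverse
lagged windows, solves the generalized eigenproblem through
$C_0^{-1/2}$, ridge-regularizes a singular $C_0$ (ε = 1e-8, with a
warning), and normalizes eigenvectors to unit instantaneous variance so
training projections are whitened. The free-energy surface is
$-kT\ln\rho$ on the first two components with empty bins kept as
infinities; `count_fes_basins()` finds local minima with a prominence
and an `fmax` cap so sparsely populated tail bins cannot masquerade as
metastable states.

Toy-scale defaults (25–50 microstates, lag chosen where implied
timescales plateau) sit alongside the frozen `"paper"` preset (1000
microstates, 5 ns lag, 1 ns tICA lag, 4 components) in
`pipeline_config()`.

# Boltzmann docking and pose triage

Each pose maps through its conformation to a microstate; the state's
stationary probability is split *uniformly* across that state's poses
(π̂), which conserves probability when many frames land in one state.
The default ranking is the effective free energy $G = g - kT\ln\hat\pi$
at kT = 0.596 kcal/mol (300 K); a linear π-weighted mode is provided
because the reweighting lineage admits both conventions, and the choice
is recorded in the output metadata. With uniform π the ranking provably
reduces to the raw-score ranking, and duplicating a state's poses leaves
the binding constant $K = \sum\hat\pi_i e^{-g_i/kT}$ unchanged — both
are asserted in tests.

Pose clustering is quality-threshold: repeatedly take the pose with the
most neighbours within the RMSD cutoff (2.5 Å at full scale) as a
representative, remove its cluster, repeat; ties go to the lowest pose
id, making the result order-independent. Ligand RMSD between poses is
computed without superposition since poses share a receptor frame.

# Stability screening and accessibility

"Remained stable throughout" is read strictly: a replicate passes only
if *every* stored frame of its ligand COM-RMSD trace is below the 15 Å
threshold, on raw (unsmoothed) traces; a pose needs at least 5 of 6
passing replicates. The strictest faithful reading was chosen and is
stated here because a smoothed or quantile-based reading would be more
permissive. Monotonicity in both threshold and `min_pass` is tested.
Contact profiles pool each pose's stable replicates before computing
per-residue frequencies (4 Å atom-pair cutoff, residues above 50%
frequency form the interacting set, strict inequality at the boundary).

Accessibility replaces Voronoi-based tunnel finding with a clearance
grid plus widest-path search: the same bottleneck semantics, far easier
to verify against analytic constructions. The grid stores, per voxel,
the distance to the nearest atom surface (0.5 Å spacing, padding ≥ a
probe diameter, default 4 Å); the tunnel search finds, per exit face of
the padded box, the path from the ligand COM maximizing the minimum
clearance (binary search over clearance levels with 6-connected flood
fills, then a breadth-first path at the optimal level). Reported
bottlenecks are accurate to about one grid spacing, and every result
carries that resolution. On grids up to 30³ the bottleneck equals an
exhaustive threshold-scan oracle exactly. "Bulk solvent" is defined
unambiguously as the padded box boundary reachable by flood fill.
Classification uses the 2.0 Å (open) and 1.5 Å (buried) thresholds with
the gap reported as *indeterminate* rather than silently resolved.
Pocket volume counts region voxels clearing the probe that are *not*
connected to bulk, times the voxel volume; a sealed spherical cavity
reproduces fine-lattice quadrature within 5% and the nominal
$\tfrac43\pi r^3$ within the lattice-gap correction.

# Pharmacology

`fit_hill()` fits the four-parameter Hill equation in log-concentration
space by Levenberg–Marquardt from a multi-start grid (five logEC50
values spanning the data range × Hill coefficients 0.5, 1, 2, 4),
keeping the lowest converged residual — the optimizer used at full scale
is undocumented, so robustness was preferred over cleverness. Noise-free
data are recovered to 1e-6 relative; `ec_fraction()` inverts the curve
analytically; `compare_groups()` runs unpaired equal-variance Student's
t tests per concentration with means ± SEM, flags zero-variance cases,
and reports p-values *unadjusted* (no multiple-comparison correction is
applied, and the output says so). Per-experiment I/I_max normalization
(`normalize_by_max()`) precedes pooling.

# Pipeline orchestration and problem sizes

`run_pipeline()` executes sampling → featurize → msm → reweight →
cluster → screen → access → report with stage-dependency checks, one
root seed feeding named per-stage child streams, and a manifest of
parameter hashes and artifact MD5s (hashed in radix-sorted order so the
manifest is locale-independent). Toy mode runs the demo end to end; with
external data the stage functions are called directly on user feature
and score tables, since driving MD or docking engines is out of scope
(adapter signatures are defined by `toy_engine()`).

Problem sizes used throughout the tests and the demo were chosen so the
whole suite exercises every stage in a few minutes on one core: 8–10
generations × 5 simulations × 400 steps of toy sampling (1600 stored
frames), 25 microstates, 10^5-step chains for estimator-recovery checks,
10^6-step trajectories for equilibrium checks, 0.5 Å grids of roughly
130 × 56 × 56 voxels for the two-site receptor, and 4000-replicate null
simulations for the t-test calibration.

# Known limitations

* The toy landscape is two-dimensional with a single slow coordinate;
  it cannot probe feature-selection failures in high dimension.
* The grid tunnel search reports bottlenecks only to grid resolution
  (±spacing) and uses 6-connectivity; very narrow oblique channels can
  be under-resolved at coarse spacing.
* π-reweighting assumes one best pose per conformation and uniform
  π-sharing within a microstate; score-dependent sharing is not
  implemented.
* The Hill fitter assumes additive homoscedastic noise; weights are
  accepted but no variance model is estimated.
* The adaptive-sampling efficiency result is a property of the bundled
  landscape and budget (win probability ≈ 0.75 per paired repeat); it
  is not a general guarantee about reward-driven sampling.
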