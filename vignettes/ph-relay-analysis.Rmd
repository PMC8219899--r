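---
title: "Models and methods: quantifying pH-sensitive calcium release"
author: "phrelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying pH-sensitive calcium release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrelay)
```

## The scientific problem

C-type lectins such as langerin recognise pathogens through a Ca²⁺ cofactor
and must release both cargo and cofactor when the receptor is internalised
into the mildly acidic endosome. The working model this package supports
quantitatively is a *pH relay*: a solvent-accessible histidine senses the
pH 7 → 6 drop; its protonation reorganises the hydrogen-bond network
between the two loops flanking the Ca²⁺ site; a lysine side chain is
thereby freed to hydrogen-bond to a Ca²⁺-coordinating aspartate, moving a
proton donor into the binding pocket; the weakened coordination lowers the
Ca²⁺ affinity, and protonation of the aspartate both blocks rebinding and
accelerates unfolding of the loop that completes the coordination cage.

Testing this model requires several quantitatively different analyses —
conformational-ensemble comparison, kinetic modelling, non-equilibrium
pulling statistics, survival analysis, ensemble pKa statistics and binding
thermodynamics. `phrelay` provides all of them behind a single set of
containers, together with a synthetic-data module that generates every
input with known ground truth, so the entire chain is testable end to end
without access to raw multi-microsecond MD data.

## Units, conventions

All quantities are in nm, ns, K and kJ/mol; forces in kJ/(mol nm). Frames
are 0-based and the time of frame *i* is *i·Δt*. The Boltzmann constant is
0.0083144621 kJ/(mol K); binding free energies use R = 8.314 J/(K mol).
Free energies are displayed at one decimal, rounded half away from zero —
the convention in which the reference dissociation constants are reported.

## Synthetic dynamics and the grid oracle

`generate_langevin()` integrates the overdamped Langevin equation

$$dx = -\frac{\nabla U}{\gamma}\,dt + \sqrt{\frac{2k_BT}{\gamma}}\,dW$$

with the Euler–Maruyama scheme. The friction coefficient γ is
parameterised directly in kJ ns/(mol nm²), so the diffusion coefficient is
D = k_BT/γ (nm²/ns) without reference to a particle mass — with γ = 1 and
T = 300 K, D ≈ 2.5 nm²/ns, a realistic scale for a collective protein
coordinate. The integrator rejects time steps violating
dt·max|U''|/γ < 0.1 and aborts explicitly if the walker leaves a generous
bounding box: silent divergence is never an acceptable failure mode of a
generator whose output seeds every downstream test.

The stationary density of this process is ∝ exp(−U/k_BT), which gives two
free checks: equipartition in a harmonic well (variance k_BT/κ) and a χ²
test of the position histogram against the Boltzmann weight. The *slowest
relaxation timescale* is computed by an independent oracle,
`grid_relaxation_time()`: the 1D domain is discretised into ≥ 500 bins and
the diffusion replaced by a nearest-neighbour jump process with rates
q(i→i±1) = D/h² · exp(−(U_{i±1}−U_i)/2k_BT), which satisfies detailed
balance by construction; the relaxation time is −1/λ₂ of the rate matrix.
The oracle shares no code with the Markov-model estimators it validates.

The remaining generators plant: rupture forces drawn from a normal cohort
on a linear loading ramp (the planted maximum is inserted noise-free so
that the noiseless case is exact); exponential unfolding times censored at
a fixed simulation cap; one-site ITC thermograms from the exact
ligand-conservation quadratic with the cell-displacement recursion;
per-frame pKa values with a Bernoulli coupling flag and two alternative
values per coupled frame; and a three-state hidden Markov chain emitting
miniature donor–hydrogen–acceptor geometries plus state-dependent reporter
atoms, so both hydrogen-bond detection and clustering can be checked
against known labels.

### Default study conditions

The demo study (`make_demo()`) fixes the synthetic conditions to the scales
of the reference study: 40 pulling traces per condition with a planted
150 kJ/(mol nm) median rupture-force offset between the neutral and
aspartate-protonated conditions and 5% force noise; 60 unfolding
trajectories per condition censored at 220 ns with planted half-lives of
218 ns (histidine protonated) and 93 ns (histidine + aspartate
protonated); a 74% planted carboxyl–carboxyl coupling fraction with
coupled-frame pKa of 6.4 ± 0.7; and the measured dissociation-constant
table (105/800 µM wildtype, 35/125 µM H294A, 108/742 µM E261D at
pH 7/pH 6, plus a remeasured wildtype pair). Where a scale is not dictated
by those measurements (e.g. the double-well barrier of the demo ensembles,
4–6 k_BT) it was chosen once as a realistic metastable regime that
exchanges often enough to be estimable at desk scale, and not revisited.

## Trajectory features

Distances, minimum group distances, RMSD and RMSF are computed directly
from the coordinate arrays and are tested against naive-loop oracles.
Superposition uses the Kabsch SVD solution; degenerate fit selections
(fewer than three non-collinear atoms) are rejected because the rotation is
then undetermined.

The hydrogen-bond criterion is the common geometric MD convention —
donor–acceptor ≤ 0.35 nm *and* hydrogen–donor–acceptor angle ≤ 30° — since
no universally agreed criterion exists; both cutoffs are arguments and are
echoed into every result object. Occupancies weight every frame equally.
A selector mini-grammar (`"K257s"`, `"N287m"`) names side- and main-chain
atom sets in the notation used for hydrogen-bond labels; main chain is
N, H, C, O, side chain the non-backbone heavy atoms plus polar hydrogens.

Histograms are computed per replica and averaged; the confidence band
resamples *replicas*, not frames, because frames within one MD trajectory
are strongly correlated and frame-level bootstraps would be spuriously
narrow. With the small replica counts typical of MD studies the plain
percentile interval itself is measurably narrow (≈ 89–90% coverage for a
nominal 95% band at 10 replicas, uniformly across bins); the band therefore
defaults to Hesterberg's expanded percentile quantiles,
α′ = Φ(−t_{R−1,α}·√(R/(R−1))), which restores ≈ 94% coverage in the same
setting. `expand = FALSE` recovers the uncorrected percentile band.

Two pooling conventions coexist deliberately: histograms are per-replica
first (each replica is one observation of the density), while population
fractions and hydrogen-bond occupancies pool frames with equal weight —
these match the two distinct conventions used for the corresponding
published quantities.

## Dimensionality reduction

`fit_pca()` is an eigendecomposition of the pooled covariance of
mean-centred features (via `stats::prcomp`). Fitting one PCA on the pooled
frames of *both* protonation-state ensembles yields a joint space in which
the two ensembles are directly comparable; when the ensembles share their
covariance structure, the joint and per-ensemble principal axes coincide
(tested as |cos| > 0.99), which justifies interpreting joint components.

`fit_tica()` solves C(τ)v = λC(0)v with the symmetrized
(forward-plus-backward) lagged covariance estimator. Symmetrization forces
a real spectrum on finite data at the cost of a small bias — the right
trade for a diagnostic of slow processes. C(0) is regularised with
εI, ε = 10⁻⁶·trace/dim, so perfectly collinear features (routine when
distances are redundant) cannot break the Cholesky factorisation; the test
suite verifies that duplicating a feature changes no eigenvalue beyond
10⁻⁶. Eigenvalues relate to relaxation timescales by t = −τ/ln λ, and for
a two-state hidden process with exchange time t* the leading eigenvalue is
exp(−τ/t*) up to an attenuation factor s²/(s²+σ²) from emission noise σ
around state means separated by 2s — the closed form used in the tests
with near-noiseless emissions.

Free-energy surfaces are −k_BT ln p on a 2D histogram with the minimum
shifted to zero; empty bins stay `NA` (masked) and are never interpolated,
because interpolating unvisited regions invents free energies. Difference
densities subtract normalized populations and therefore integrate to zero.

## Common-nearest-neighbours clustering

Conformational states are extracted with density-based
common-nearest-neighbours (CNN) clustering: a and b are density-connected
iff |a−b| ≤ r *and* their r-neighbourhoods share ≥ n_c points; clusters
are connected components of this relation; isolated points and components
below `min_members` are noise. Requiring *mutual* r-membership in addition
to the shared-neighbour count keeps the relation symmetric. The parameters
have no defensible universal defaults, so they must be supplied explicitly.

The neighbour search is exact — a uniform cell grid in ≤ 3 dimensions,
chunked brute force otherwise — never approximate, so the algorithm can be
(and is) tested for *exact* label agreement against an independent dense
matrix-algebra implementation on randomized instances up to 2000 points.
Labels are deterministic: sorted by size, ties by smallest member index.

## Core-set Markov models

Cores are the non-noise clusters (in 1D, the member interval; otherwise
membership within r of any member). Milestoning assigns out-of-core frames
to the *last visited* core, the causal approximation to committor-based
assignment; frames before the first core visit are discarded rather than
back-filled, keeping the assignment causal. Transition counts use a
sliding window at lag τ, never crossing replica boundaries.

Estimation is reversible-by-symmetrisation: C′ = (C+Cᵀ)/2 restricted to
the largest strongly connected component, then row-normalised. This
guarantees a real spectrum, detailed balance (π_i T_ij = π_j T_ji, tested
to 10⁻⁸) and a closed-form stationary distribution (normalised row sums of
C′). An iterative reversible MLE would squeeze slightly more out of sparse
counts but adds an optimisation loop that desk-scale data do not need; the
estimator is isolated behind `estimate_msm()` as an extension point.

The implied-timescale test re-estimates the model over a ladder of lags
and flags each process converged when its relative spread over the upper
half of the ladder is ≤ 20% (configurable). The end-to-end validation —
Langevin double well → CNN cores → milestoning → counting → estimation —
recovers the grid oracle's relaxation time within 15% and is
lag-independent, which is the property that certifies the whole chain
rather than any single stage. Problem sizes used in the tests (10⁶–6·10⁶
integrator steps, 1500-point clustering subsamples, four lags) were chosen
as the smallest that leave comfortable statistical margin for those
bounds.

## Rupture-force analysis

Constant-velocity pulling traces are smoothed with a centred moving
average (default 0.1 ns); the rupture is the smoothed maximum, accepted
only if the smoothed force afterwards stays below `drop_fraction` (default
0.5) of that maximum for at least `sustain` (default 0.5 ns). The
published analyses locate rupture events visually; this rule is the
package's operationalisation of the "sudden force drop", and all three
parameters are echoed into every result. A monotone trace yields
`detected = FALSE`, not an error — undetected traces are data, counted and
reported per cohort.

Cohorts are summarised as notched boxes: quartiles by linear interpolation
(R type 7; the convention is stated in the output because quartile
conventions differ across tools), notch 1.57·IQR/√n, outliers beyond
1.5·IQR. Pairwise median differences carry percentile-bootstrap intervals.

## Unfolding kinetics

Unfolding events are classified from feature time series: RMSD exceeding
0.2 nm, or a named hydrogen bond continuously broken, sustained for at
least `persistence` (default 1 ns — brief recrossings are not unfolding
events). Trajectories without an event are right-censored at their end.
Purely visual criteria cannot be automated faithfully and are accepted
only as externally supplied annotations.

The decay fit is the censored-exponential MLE, k̂ = d/Σt (d events, all
observed times in the denominator), chosen over least squares on the decay
curve because it uses censored information correctly and has closed-form
uncertainty (σ_k = k̂/√d; delta method for t₁/₂); the least-squares fit is
available via `method = "ls"` for comparison. A Kolmogorov–Smirnov
distance of the event times to the fitted (cap-truncated) exponential is
always reported, as real unfolding decays can deviate from
single-exponential behaviour when intermediates are present; the package
deliberately does not fit multi-exponential models.

## Ensemble pKa aggregation

`parse_propka()` ingests PROPKA 3.1 summary output (one file per frame);
the package never computes pKa from structure — that is the upstream
predictor's job. Coupled carboxyl pairs carry two alternative values
(a: this group protonated first and stabilised by the partner; b: the
reverse), whose labels are preserved from the file, never inferred.
Aggregation reports per-residue mean ± SD over all frames and over
coupling frames, the coupling percentage, and the fraction of the
distribution inside the critical pH 6–7 window — the range in which a
group can act as a physiological pH sensor. "Reaches into the window" is
operationalised as window mass > 1% (configurable), since the qualitative
phrase needs a threshold to be testable.

## Binding thermodynamics

ΔG = RT ln K_d (K_d in mol/l, dimensionless under the 1 M standard state)
and ΔΔG = ΔG(pH 6) − ΔG(pH 7), with first-order error propagation
(σ_ΔG = RT·σ_K/K). Full precision is kept internally; display rounds to
one decimal, half away from zero. `fit_one_site()` fits the same exact
one-site isotherm the generator uses (quadratic solution of ligand
conservation with the displacement recursion, Hill coefficient fixable to
1) by Levenberg–Marquardt least squares on log K_d. The Wiseman parameter
c = n·[cell]/K_d is always reported: below c ≈ 5 the isotherm is too
shallow to pin down the enthalpy, so the fit flags ΔH as unreliable while
K_d itself remains recoverable (tested to 20% at c = 2 with 2% heat
noise).

## What the synthetic tests do and do not show

The synthetic module emulates the *statistical structure* of the real
inputs — metastability with known exchange rates, censored exponential
events, planted cohort offsets, known coupling fractions — not their
physics. Passing tests therefore demonstrate that the estimators are
correct and well-calibrated on data of the right shape and size; they do
not validate force fields, sampling convergence of real MD, or the
structural interpretation of any particular cluster. Quantities that
depend on the unavailable raw trajectories (specific state populations,
microsecond timescales, absolute rupture forces) are represented by
planted analogues at the published scales, not reproduced.

## Known limitations

- tICA and PCA are linear; strongly nonlinear slow coordinates would need
  kernel or state-space methods that are out of scope.
- The reversible MSM estimator is symmetrisation-based; Bayesian error
  bars and transition-path analyses are not provided.
- CNN clustering is exact but O(n²) in the worst case; subsample before
  clustering very long trajectories (the pipeline does).
- XTC trajectories are not read; use multi-model PDB, GRO or DCD.
- The rupture detector assumes a single dominant rupture event per trace.
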