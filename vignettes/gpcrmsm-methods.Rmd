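---
title: "Models and methods in gpcrmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gpcrmsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrmsm)
```

`gpcrmsm` turns collections of molecular dynamics trajectories of a
G-protein-coupled receptor into a quantitative picture of its activation:
which conformational states exist, how populated they are, how fast they
interconvert, and which structural motions are allosterically coupled. This
vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the bundled synthetic-data validation can
demonstrate.

## Contact-score featurization

A conformation is described by residue–residue contact scores (RRCS). For
every residue pair with sequence separation greater than one helical turn
(|i − j| > 4 residues), the score sums a piecewise-linear kernel over
heavy-atom pairs at distance d:

- s(d) = 1 for d ≤ 3.23 Å,
- s(d) = 0 for d ≥ 4.63 Å,
- s(d) = (4.63 − d)/1.40 in between.

Hydrogens are always ignored; no crystallographic occupancy weighting is
applied, since the inputs here are MD or synthetic frames rather than
crystal structures. The separation cutoff implements "more than one helical
turn" as four residues, the length of one α-helical turn. Feature selection
compares the RRCS matrices of an active and an inactive reference and keeps
the Cα distance of every pair whose score changes by **strictly more than
3** (the threshold is exclusive): these are the contacts that form or break
during activation.

Named features complement the contact set where the activation mechanism is
known: minimum heavy-atom distances, the χ2 side-chain dihedral of the
toggle-switch tryptophan (atom quadruple fixed to CA–CB–CG–CD1, the
tryptophan convention, reported in degrees wrapped to (−180°, 180°]), and
the z-displacement between the side-chain centres of mass of the twin
toggle-switch residues, signed as z(first residue) − z(second).

The binding-pocket volume is a deliberately simplified probe-excluded grid
count: voxels (default 1 Å) inside an inclusion sphere centred on the mean
Cα of user-chosen pocket residues, farther than (van der Waals radius +
1.4 Å probe) from every heavy atom. It tracks the *trend* of pocket
expansion and contraction across states; it does not reproduce flood-fill
contiguity machinery of dedicated pocket-volume tools, and absolute values
should not be compared across software.

## From features to a Markov state model

Dimensionality reduction uses time-lagged independent component analysis
(tICA) with symmetrized (reversible) lagged covariances — the forward and
time-reversed estimates are averaged — and a ridge of 1e-6 on the
instantaneous covariance diagonal so duplicated or constant features remain
solvable. Components are sorted by autocorrelation eigenvalue.

Microstates come from k-means in tIC space with k-means++ initialisation;
all randomness flows through one seed, so clustering is reproducible.
Least-count adaptive-sampling seeding (`least_count_seeds`) returns restart
frames from the least-populated clusters, round-robin in ascending
population order with ties to the lower cluster index.

The MSM estimator counts sliding-window transitions at lag τ and, in the
default reversible mode, symmetrizes counts as (C + Cᵀ)/2 before
row-normalising. This closed-form estimator satisfies detailed balance
*exactly* and makes the stationary distribution the normalised symmetrized
row sum — a deliberate departure from the iterative maximum-likelihood
reversible estimators in mainstream MSM software, chosen because it is
exactly testable; on well-sampled data the two agree closely. Counting is
restricted to the largest connected set (undirected connectivity for the
reversible estimator, strong connectivity otherwise). Eigenvalues are
sorted by magnitude; a negative eigenvalue enters the timescale formula
t = −τ/ln|λ| through its absolute value and is flagged.

The default physical lag is 25 ns (`build_msm`), converted to frames via
the frame interval; implied-timescale convergence across lags and the
Chapman–Kolmogorov test (model propagated k lags versus re-estimated at
lag kτ, with trajectory-bootstrap uncertainty bands) validate the choice.
Hyperparameters (number of tICs, number of microstates) are scored by
10-fold cross-validated VAMP-2: the training model's eigenvectors define a
subspace, the symmetrized held-out covariances are projected into it, and
the squared generalized eigenvalues are summed (the stationary eigenvalue
is included, so a connected chain scores ≥ 1). With train = test this
reproduces Σλ² of the training model exactly. Ties break toward fewer
clusters, then fewer tICs. One caveat: tICA and clustering are fitted once
on the full data and only the VAMP-2 evaluation is cross-validated, so the
score guards against overfitting of the *spectral* content, not of the
discretization itself.

## Metastable states

Microstates are coarse-grained into m metastable states by spectral soft
clustering on the top-m right eigenvectors: the m microstates spanning the
eigenvector simplex become vertices and every other microstate receives a
membership row by linear inversion, clipped to [0, 1] and renormalised.
This deterministic construction replaces a neural-network soft classifier
for the same task; it is evaluated under the same two state-count criteria,
so every downstream claim (state count, populations, per-state statistics)
remains testable, while removing stochastic training from the analysis
surface. For near-block-structured chains the memberships are nearly crisp;
crisp assignment is argmax membership with ties to the lower state index.

The number of states is selected by two criteria: (1) every metastable
state must hold at least 4% of the stationary population — candidates
violating this are discarded; (2) among the survivors, the candidate
minimising the bootstrap standard deviation (20 resamples of 80% of
trajectories) of the slowest coarse-grained implied timescale wins. The
criteria do not specify which timescale or resampling scheme to use, so
this module reads "minimum error bar" as the absolute bootstrap SD of the
slowest timescale of the membership-projected transition matrix; the full
per-candidate report is returned so a different reading can be applied.

Representative frames per state are drawn with probability proportional to
π_i · χ_is of their microstate (1000 frames per state for divergence
analyses; 100 is the conventional choice for docking-style downstream use).
Sampling is without replacement unless a state holds fewer frames than
requested, in which case replacement is used and flagged.

## Kinetics

Transition path theory between metastable states A and B (realized as
microstate sets by crisp membership): the forward committor solves the
harmonic linear system with q = 0 on A and q = 1 on B; the gross reactive
flux is f_ij = π_i (1 − q_i) T_ij q_j, the net flux its positive
antisymmetric part, the total flux F the gross flux out of A, and the mean
first passage time MFPT = τ Σ_i π_i (1 − q_i) / F. The package also ships
the empirical counterpart (`empirical_passage_times`): label every frame of
an equilibrium trajectory by the core last visited and average the
durations from each B→A arrival to the next A→B arrival. The two agree
within sampling error on every chain tested, which is the package's
strongest internal consistency check.

Kinetic Monte Carlo follows the cumulative-distribution algorithm: build
the cumulative transition probabilities S of the current row, draw R in
[0, 1), jump to the first state with R < S, advance time by τ. R is drawn
in [0, 1) with a strict comparison, which differs from any closed-interval
reading only on a measure-zero set. The chain kernel is compiled (Rcpp) and
uses R's RNG, so `set.seed` governs reproducibility. The conventional start
state for activation ensembles is the inactive state's highest-membership
microstate (`kmc_start_state`).

## Allostery and divergence statistics

**Conditional coupling.** Each feature is binarized by a threshold
(conventionally the midpoint of the active and inactive reference values;
the direction flag says which side counts as active), and the statistic is
|P(F_i active | F_j active) − P(F_i active | F_j inactive)| under MSM
equilibrium frame weights. Both ordered entries (i|j and j|i) are reported,
since the statistic is not symmetric. A conditioning side with zero weight
yields NA, never a silent 0.

**Residue-KL profiles.** For every residue pair, the closest-heavy-atom
distance distributions of two metastable states are compared by symmetric
Kullback–Leibler divergence on shared-support histograms; a residue's value
is the mean over all pairs involving it. Methods-level texts sometimes
restrict to carbon atoms; both readings are supported (`carbon_only`),
with closest *heavy* atom as the default.

**Mutual-information pathways.** Normalized MI between dihedral features
(joint histograms; normalization by the mean of the two marginal entropies,
clipped to [0, 1]; constant dihedrals yield NA) feeds a residue contact
graph (edges where closest heavy atoms are within 5 Å) with edge weights
MI_max − MI_ij. Minimum-weight paths are computed for every residue pair at
least 12 Å apart (closest-heavy-atom distance in the representative
structure, consistent with the contact rule), ranked by cumulative MI, and
the top 500 retained. Path clustering uses Jaccard distance on residue
sets, average linkage, and silhouette-selected cluster count — fixed here
because the upstream literature delegates the choice to prior work without
a formula.

## Histogram estimators

All divergence estimators are histogram plug-ins on shared bins over the
pooled range (default 30 bins). Two numerical choices matter:

- *KL pseudocount.* KL histograms add half a count per bin
  (Jeffreys-style). A vanishing pseudocount looks harmless but lets a
  single-count tail bin opposite an empty bin contribute a term of order
  p·ln(1/ε) — with ε = 1e-10 that is ~0.05 nats per bin, swamping the null.
- *Bias correction.* The residue-KL profile subtracts the first-order
  plug-in bias (B_occ − 1)/2 · (1/n_a + 1/n_b) per pair (clamped at zero),
  so that comparing a state against itself sits at zero rather than at the
  histogram bias. The MI estimator keeps a vanishing pseudocount: empty
  joint bins contribute essentially nothing there, and the normalized
  statistic is used for *ranking* edges, where the small uniform positive
  bias cancels.

The feature-shift table (mean-shift metric plus the two KL divergences of
apo against each holo ensemble) min-max normalises each feature over the
pooled three ensembles first, so the three metrics are comparable across
features with different units.

## Error analysis

Trajectory-level bootstrap draws ⌈0.8 N⌉ trajectories without replacement,
200 times, and recomputes any statistic; frame-level bootstrap draws 1000
frames within a metastable state, 20 times. Failing samples are excluded
and counted, never silently imputed. Free-energy projections are
−kT ln(weighted density), min-shifted to zero; empty bins are reported as
NA rather than −∞; kT defaults to 1 (dimensionless), with
`kT_KCAL_300K` = 0.596 kcal/mol available for physical units.

## The synthetic-data generator

The generator emulates the statistical structure of an adaptive-sampling
MD campaign without any physics: a latent Markov chain over a small number
of metastable states with hierarchically separated exchange timescales
drives (a) Gaussian per-state feature emissions with optional pairwise
couplings (enforced by reflecting the second feature across its activity
threshold with the stated probability) and (b) pseudo-atomic coordinates
linearly interpolated between an inactive and an active toy receptor, plus
isotropic noise. Latent states map to evenly spaced interpolation weights
in [0, 1], guaranteeing distinct per-state contact distributions. The toy
receptor is a two-strand hairpin whose sequence-distant facing residues
form cross-strand contacts; perturbed residues are rigidly displaced out of
the contact plane in the active structure, and a manifest records every
pair whose contact score changes by more than the stated margin — the
ground truth for feature-selection and hotspot tests.

The default six-state reference chain has two blocks of three states with
fast within-block exchange (intra-block hop probability 0.08 per step,
relaxation ≈ 3.6 steps) and one slow doorway between the blocks. The
doorway probability (0.01 per step, slowest timescale ≈ 158 steps) was set
so that the validation sample sizes used throughout (10⁵–10⁶ transition
counts) determine the slow timescale to a few percent — deep enough a
hierarchy to be unambiguous, shallow enough to be measurable.

What the synthetic validation does *not* show about real data: emissions
are unimodal Gaussians (real per-state feature distributions can be skewed
or multimodal), coordinates interpolate linearly between two structures (no
genuinely novel intermediate geometries), there is no solvent, membrane or
force-field physics, and microstate discretization error is mild because
the latent states are well separated in feature space. Passing these tests
certifies the *estimators*, not the sampling adequacy of any particular MD
dataset.

## Problem sizes and runtimes

The test-suite simulations were sized to keep statistical error several
times smaller than each assertion's tolerance: 100 trajectories × 5000
steps for stationary/timescale recovery (≈ 2% SE on the slow timescale),
10⁶-step chains for occupancy and committor oracles, ≥ 10⁴ passage events
for MFPT comparisons, 500–1000 frames per state for divergence nulls, and
10⁴ frames for coupling and MI estimates. These sizes are choices, not
limits; every generator scales with its arguments.

## Known limitations

- The reversible estimator is the symmetrized-count closed form, not the
  reversible MLE; for very unevenly sampled state pairs the two differ.
- PCCA-style memberships use the classic inner-simplex construction
  without the subsequent objective optimisation; for strongly overlapping
  eigenvector simplices an optimised variant can be crisper, and a
  degenerate eigenvalue at the cut is reported as an error rather than
  resolved.
- Trajectory I/O reads PDB and DCD; trajectories are *written* as
  multi-model PDB (text), not DCD.
- The pocket volume is an inclusion-sphere grid count (no contiguity
  analysis); compare trends, not absolute volumes.
- Pathway search assumes a connected contact graph; disconnected endpoint
  pairs are skipped silently (they simply yield no path).
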