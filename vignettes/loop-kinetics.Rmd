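---
title: "Kinetic models of slow protein loop dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of slow protein loop dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinloops)
```

# The scientific problem

Proteins with mobile surface loops often hide their functionally
decisive motions in the microsecond-and-slower regime, where a single
molecular dynamics (MD) trajectory rarely samples more than a handful
of transitions.  Markov state models (MSMs) address this by stitching
many short, independent trajectories into one kinetic model: frames
are mapped to discrete conformational states, transition counts at a
lag time are harvested, and the estimated transition matrix yields
equilibrium populations, relaxation timescales and mean first passage
times (MFPTs) that no single trajectory could supply.  A companion
line of evidence comes from NMR: backbone amide ^15^N relaxation rates
(R1, R2, heteronuclear NOE) report on the amplitude and timescale of
local motion residue by residue.

`kinloops` implements the full analysis chain for this setting:
exhaustive residue-pair featurization with occupancy pruning,
time-lagged independent component analysis (tICA), an iterative
feature-elimination loop that discovers which residues anchor the slow
motions, microstate MSMs coarse-grained into metastable macrostates by
a hidden Markov model (HMM), side-by-side comparison of two ensembles
(say, a wildtype-like and a mutant-like system) in one shared kinetic
coordinate system, and Lipari–Szabo model-free analysis of relaxation
data.  Because real long-timescale MD datasets are huge and rarely
redistributable, the package also ships a synthetic-data generator
that plants known slow/fast loop kinetics in a toy chain molecule, so
every stage can be validated against ground truth.

# The synthetic system and what it does (and does not) emulate

`gen_toy_loop_trajectory()` builds a 3D bead chain, one bead per
residue at 3.8 Å spacing (the Cα–Cα virtual bond length).  Two
disjoint residue blocks act as loops: each interconverts between a
baseline ("recessed") and a displaced ("extended") geometry under an
independent two-state Markov chain, while all other residues only
jitter isotropically about fixed scaffold positions.  The defaults are
chosen once and define the study conditions for every test:

* 40 residues; fast block 8–12, slow block 28–33.  The two blocks give
  a 4-state product process — the minimal landscape with two
  independent slow degrees of freedom, mirroring a protein in which
  one mobile loop interconverts markedly more slowly than a second,
  faster one.
* Per-frame switch probabilities 0.01 (fast) and 0.002 (slow).
  Neither value is dictated by theory; they were fixed a priori so
  that a few thousand frames contain tens of slow transitions — the
  "barely sampled" regime MSMs exist for — while keeping a 5× kinetic
  separation between the blocks.
* Displacement 6 Å between conformations, positional jitter 0.3 Å per
  coordinate.  The generator checks the separability precondition
  (conformations must differ by more than 4× the jitter in at least
  one block–scaffold distance) and flags, rather than hides, a
  violation.

The generator returns the exact hidden transition matrix, its
stationary distribution and the full MFPT matrix
(`planted_kinetics`), plus the per-frame hidden path — so downstream
estimates are tested against *exact* truth, not against another
estimator.

What the toy does **not** emulate: real bond geometry, side chains,
solvent, anharmonic within-state dynamics, state-dependent noise, or
overlapping/correlated slow processes.  Passing the test suite
therefore demonstrates that the estimators recover planted Markovian
loop kinetics from noisy Cartesian data; it does not certify behavior
on non-Markovian or poorly separated real ensembles.

# Featurization and pruning

Features are Euclidean Cα–Cα distances for all residue pairs i < j,
labelled `D_i_j` in the 1-based numbering of the input structure.
Residues within a configurable clip width of either terminus (default
2) are excluded before enumeration: terminal fraying is fast,
high-amplitude motion that would otherwise dominate variance without
carrying slow kinetics.  For 192 eligible residues the enumeration
yields 18 336 pair features.

Pruning then removes features that are *always* closer than 3 Å or
*always* farther than 10 Å across every frame of every system
supplied: such pairs are locked contacts or permanently separated
pairs, incapable of encoding a conformational switch.  A pair that
spans the band on even one frame is retained.  When two systems are
analyzed together they are pruned together, so both share a single
feature set — a prerequisite for projecting both into one tICA space
later.

# tICA: estimator and numerical choices

For mean-free features $x_t$, tICA solves the generalized eigenproblem
$C(\tau)\,v = \lambda\, C(0)\,v$ with $C(0)$ the instantaneous and
$C(\tau)$ the lag-$\tau$ covariance.  Design choices:

* **Reversible (symmetrized) estimator.**  Both lag ends contribute to
  the mean and to $C(0)$, and $C(\tau)$ is symmetrized.  The
  downstream MSM assumes equilibrium sampling; using the matching
  covariance estimator keeps eigenvalues real and the projections
  consistent with that assumption.  Frame pairs never cross trajectory
  (or system) boundaries.
* **Regularization.**  The first pass runs on ~18k features where
  $C(0)$ is rank-deficient by construction, so `reg_epsilon` (default
  `1e-6`, relative to `trace(C0)/d`) is added to the diagonal before
  the Cholesky-based whitening.  Setting it to 0 recovers the exact
  eigenproblem when $C(0)$ has full rank (the invariance tests do
  this, because diagonal regularization is the one step that is not
  equivariant under linear feature maps).
* **Sign convention.**  Each component is flipped so its
  largest-magnitude loading is positive; eigenvalues are sorted
  descending, and implied timescales are $t_k = -\tau/\ln\lambda_k$
  for $0<\lambda_k<1$.
* **No kinetic-map scaling.**  Projections are plain mean-centered
  linear maps; the free-energy surfaces are density-based, for which
  per-component scaling is cosmetic.
* **Lag time.**  There is no universally correct tICA lag; the package
  exposes it everywhere and provides `tica_its()` to tabulate
  timescale convergence against lag.  The toy analyses use lag 2
  frames, inside the flat region of that curve for the planted chains.

A caveat that shaped the test design: the leading tICA eigenvalue is a
*variational lower bound* attenuated by measurement noise,
$\hat\lambda \approx \lambda\, s/(s+\nu)$, where $s$ is the signal
variance and $\nu$ the residual noise variance along the optimal
projection.  Feature sets of different sizes average noise differently,
so comparing raw tICA timescales across feature sets conflates
kinetics with noise averaging.  Whether feature selection *preserves
the slow process* is therefore judged on the MSM implied timescale
computed from each feature set's discretized projection — the
estimator the pipeline actually uses for kinetics — which is robust to
emission noise (both the full set and the 24-pair selection give the
planted ~250-frame timescale to within a fraction of a percent at the
tested sampling depth).

# Iterative feature selection and anchor residues

`iterative_tica_selection()` alternates: fit tICA on the surviving
features; score each feature by its maximum absolute Pearson
correlation with the first `n_tics` component time series (default 2 —
one per expected slow loop process); eliminate the weakest.  The
schedule drops the bottom half while more than $2K$ features remain,
then one feature at a time down to exactly $K$ (default 24).  Scoring
uses the projected time series rather than raw loadings because
loadings of correlated distance features are not comparable across
features, while time-series correlation is scale-free.  Determinism is
guaranteed: tICA is refit from scratch each iteration and score ties
break lexicographically by feature label.

The anchor table counts how often each residue occurs among the
selected pairs.  Equally recurrent residues are ordered by the summed
|correlation| of their pairs with tIC1, so anchors of the *slowest*
process head the table — the domain's own reading of "anchor" (on the
planted toy both blocks tie in counts by symmetry, and the slow block
correctly leads).  `anchor_report()` keeps the simpler
count-then-index ordering for thresholded reporting.

# Microstate MSM and HMM coarse-graining

The tIC projection is discretized by seeded k-means (k-means++
initialization; k is configurable, 20–100 in the shipped analyses).
Transition counts use the sliding window at lag $\tau$, restricted to
the largest strongly connected set.  The reversible
maximum-likelihood transition matrix comes from the standard
self-consistent iteration on the flux variables
$x_{ij} \leftarrow (C_{ij}+C_{ji})\,/\,(C_i/x_i + C_j/x_j)$,
converged at a maximum relative flux change of $10^{-10}$; detailed
balance holds exactly at every iterate by construction.  Validation
helpers: `implied_timescales()` across lags (Markovian data plateau)
and `ck_test()` (Chapman–Kolmogorov propagation vs re-estimation).

The macrostate count is chosen by the spectral-gap rule: with implied
timescales sorted slowest-first, the model keeps $1 + \arg\max_k
(t_k/t_{k+1})$ states, i.e. all processes above the widest gap; an
explicit user override always wins, and a gap ratio below 1.5
triggers an error rather than a silent guess.

Coarse-graining estimates a discrete-output HMM: PCCA+ memberships of
the reversible microstate matrix (inner-simplex construction on the
dominant right eigenvectors) initialize the hidden transition and
emission matrices, and Baum–Welch refines them until the
log-likelihood gain drops below $10^{-6}$ (forward–backward E-step in
compiled code; at lag > 1 the observation sequences are strided so
each lag-spaced transition is used once).  Macrostate populations are
the hidden chain's stationary distribution — chosen over frame counts
because the HMM corrects for misassigned boundary frames.  MFPTs
between macrostates solve the first-passage linear system on the
hidden matrix and are reported in physical time via the lag and frame
interval.

Uncertainties come from a bootstrap over whole trajectories (the unit
that respects temporal correlation), re-estimating the HMM per replica
and matching macrostates back to the reference model by maximal
membership overlap before accumulating SDs.  With a single trajectory
the package falls back, loudly, to a block bootstrap over contiguous
segments.  On the planted toy (20 trajectories, 100 replicas) the
true populations fall within ±2 bootstrap SDs for ≥90% of macrostates
across seeds — the calibration the acceptance checks assert.

# Comparing two ensembles

Both systems are projected with one tICA model fitted on their pooled
segments (`joint_tica()`), which makes the coordinate space shared by
construction.  Transition statistics are never mixed across systems —
only covariances for the common projection are pooled.  Macrostates of
the two per-system HMMs are then matched greedily by centroid distance
in the shared tIC plane; candidate pairs farther apart than a
threshold (default: half the median inter-centroid distance) stay
unmatched and are reported as system-exclusive states.  Geometric
matching was chosen over membership overlap because the systems have
disjoint trajectories, so their microstates never co-occur.
`compare_kinetics()` reports population shifts with bootstrap SDs
propagated in quadrature, and MFPT ratios for every ordered pair of
matched states; a shift is flagged when the ±2 SD intervals do not
overlap.  Reference conformations (e.g. crystal structures) are placed
on the same landscape by computing their feature vector and projecting
with the shared model.

# NMR relaxation analysis

The forward model is the standard Lipari–Szabo spectral density
$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
\frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right]$,
$1/\tau' = 1/\tau_m + 1/\tau_e$, combined into R1, R2 and NOE through
the usual dipolar and CSA terms at
$\{0, \omega_N, \omega_H\pm\omega_N, \omega_H\}$, with an additive
exchange term $R_{ex}$ on R2.  Constants are fixed and documented
(N–H bond length 1.02 Å, ^15^N CSA −172 ppm, standard gyromagnetic
ratios); the default field is 800 MHz.  The implementation was
verified against an independently written implementation of the same
textbook expressions to 10^−12^.

* `estimate_tm()` inverts the rigid-limit R2/R1 ratio per residue
  (monotone in $\tau_m$, solved by bisection on 0.5–100 ns) and takes
  the median over residues retained by the trim rule: R2/R1 within
  mean ± 1 SD and NOE ≥ 0.65, which removes exchange-broadened and
  highly mobile residues.  Isotropic tumbling only: an axially
  symmetric diffusion tensor needs per-residue bond orientations from
  a structure and is out of scope here.
* `modelfree_fit()` fits each residue by error-weighted least squares
  over the nested models S²; S²+τe; S²+τe+Rex, with multi-start
  bounded optimization, and selects the simplest model that no more
  complex candidate improves by more than Δχ² = 4.6.  The comparison
  is against the *best* of the more complex models: an
  exchange-dominated residue gains nothing from τe alone, and a
  strictly sequential rule would strand it at the rigid model.
* `classify_r2r1()` implements the qualitative map: residues above the
  global mean + 1 SD of R2/R1 are "slow" (μs–ms exchange), below mean
  − 1 SD "fast" (ps–ns), the rest "typical".

# Problem sizes and numerical tolerances in the shipped analyses

The validation analyses run on deliberately modest problem sizes — the
smallest at which each estimator's sampling error is comfortably
inside the asserted tolerance: 6–20 trajectories of 1500–2000 frames
for the geometric toy (tens of slow transitions), 2×10^5 frames for
spectral-recovery checks, 10^5 replicas for first-passage simulation,
100 bootstrap replicas for population SDs.  Emission noise in the
spectral-recovery fixtures is set to 0.05 of the state separation so
that the variational attenuation described above (≈ s/(s+ν)) is an
order of magnitude below the 15% recovery tolerance being checked —
the check is about spectral estimation, not noise robustness, which is
exercised separately on the noisier geometric toy.

Degenerate inputs are contracts, not corner cases: non-stochastic or
reducible transition matrices, lags not below the shortest segment,
all-pruned feature sets, empty macrostates after Baum–Welch (retried
once from a crisp PCCA+ assignment, then an error), unreachable MFPT
targets (error naming the unreachable states), constant features in
correlation (zero with a flag, not NaN), and zero measurement errors
in fitting (unit weights instead of division by zero).

# Known limitations

* The HMM assumes the macrostate process is Markovian at the chosen
  lag; strongly non-Markovian data will pass through but fail
  `ck_test()` — run it.
* MFPT point estimates inherit discretization bias from k-means
  microstates; ratios between systems cancel much of it (the shipped
  comparison recovers a planted 2× rate change within ~10–25%), but
  absolute MFPTs at coarse discretization can be biased high.
* Geometric macrostate matching can mispair states if two landscapes
  differ by large coordinated shifts of all basins; the threshold and
  the centroid table are exposed so such cases are visible.
* The model-free module fits isotropic tumbling only and three motion
  models; anisotropic diffusion, spectral density mapping and
  relaxation dispersion are out of scope.
* DCD and multi-model PDB are the supported trajectory formats (plus
  feature CSVs); XTC is not read.
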