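# kinloops

Kinetic analysis of slow protein loop dynamics from molecular
dynamics ensembles and NMR relaxation data.

## What problem this solves

Functionally important loop motions in proteins often live on
microsecond-and-slower timescales that individual MD trajectories
barely sample.  Markov state models (MSMs) recover those kinetics by
pooling many short trajectories: frames are discretized into states,
transition counts at a lag time τ are harvested, and the estimated
row-stochastic matrix T yields equilibrium populations π (from
πT = π), implied relaxation timescales t_k = −τ/ln λ_k, and mean
first passage times (MFPTs, by a linear solve of the first-passage
system m_i = 1 + Σ_{j∉target} T_ij m_j).  NMR backbone relaxation
(R1, R2, ¹⁵N NOE) provides the orthogonal, per-residue experimental
view of the same motions through Lipari–Szabo model-free analysis
(order parameters S², internal times τe, global tumbling τm) and the
qualitative R2/R1 timescale classification.

`kinloops` implements that entire chain for researchers studying
conformational ensembles of loop-bearing proteins (e.g. comparing a
wildtype and a point-mutant ensemble):

* exhaustive Cα–Cα pairwise-distance featurization, with terminal
  clipping and pruning of pairs that stay <3 Å or >10 Å on every
  frame;
* time-lagged independent component analysis (tICA) with the
  reversible covariance estimator, solving C(τ)v = λC(0)v;
* iterative tICA-correlation feature elimination, reducing ~10⁴
  candidate pairs to a compact kinetically relevant set and reporting
  recurrent **anchor residues** of the slow motions;
* microstate MSMs (seeded k-means, reversible maximum-likelihood T,
  implied timescales, Chapman–Kolmogorov validation, free-energy
  surfaces −kT ln p over the leading tICs);
* HMM coarse-graining into metastable macrostates (PCCA+
  initialization + Baum–Welch), with populations ± bootstrap SD and
  macrostate MFPTs;
* two-system comparison in one shared tICA space: matched, abrogated
  and exclusive states, population shifts, MFPT ratios, and
  projection of reference structures onto the landscapes;
* model-free NMR analysis: forward model, τm estimation from the
  rigid R2/R1 ratio, per-residue (S², τe, Rex) fits with model
  selection, and mean ± 1 SD R2/R1 classification into slow (μs–ms),
  fast (ps–ns) and typical residues;
* a synthetic-data generator planting known two-loop Markov kinetics
  (and forward-modelled relaxation data) so every stage is testable
  against exact ground truth.

## Worked example

Generate a toy ensemble whose "slow loop" (residues 28–33) switches
conformation five times more slowly than its "fast loop" (8–12), then
run the full pipeline:

```r
library(kinloops)

se <- gen_toy_loop_trajectory(n_traj = 8, n_frames = 2000, seed = 42)
se$ensemble
#> trajectory ensemble: 8 trajectories (2000+...+2000 frames), 40 residues, dt = 1 ns

defs <- enumerate_ca_pairs(topology(se$ensemble$topology$residues,
                                    terminal_clip = 2))
nrow(defs)                       # all eligible pairs: C(36, 2)
#> [1] 630

fm     <- compute_features(se$ensemble, defs)
pruned <- prune_features(fm)     # drop always-<3A / always->10A pairs
length(pruned$pruned$labels)
#> [1] 101

sel <- iterative_tica_selection(pruned$pruned,
                                selection_config(lag = 2, K = 24))
sel
#> feature selection: 24 pairs selected (converged) in 5 iterations
#> top anchors:
#>  residue count tic1_score
#>       27     3  2.7757602
#>       33     3  2.7715247
#>       34     3  2.7696714
#>       12     3  0.5285682
#>        8     3  0.5264006
```

The top anchors sit in (or flank) the planted slow block — the
generator's analog of discovering that one specific loop carries the
protein's slowest motions.  Continue to the metastable model:

```r
idx   <- match(sel$selected$label, pruned$pruned$labels)
selfm <- feature_matrix(pruned$pruned$values[, idx],
                        sel$selected$label, pruned$pruned$segments)
proj  <- tica_project(sel$model, selfm)

dtraj <- cluster_microstates(proj, k = 20, seed = 7,
                             segments = selfm$segments)
its   <- implied_timescales(dtraj, lags = 2, n_its = 6)
select_macrostate_count(unlist(its[1, -1]))   # spectral-gap rule
#> [1] 4

meta <- coarse_grain_hmm(dtraj, 4, lag = 2)
meta <- population_uncertainty(dtraj, meta, n_boot = 50, seed = 11)
meta
#> metastable model: 4 macrostates (HMM at lag 2, dt 1)
#>   populations: 0.171 +/- 0.040, 0.232 +/- 0.042, 0.286 +/- 0.051, 0.311 +/- 0.043

macro_mfpt(meta, 1, 4)$mfpt
#> [1] 461
```

The gap rule recovers the planted 4-state product process; the true
populations (0.25 each) lie within two bootstrap SDs of every
estimate, and macrostate MFPTs come with bootstrap uncertainties.
`run_pipeline()` chains all of the above (plus the two-system
comparison and the relaxation branch) from a single config list or
YAML file and writes every stage's artifacts and a manifest.

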