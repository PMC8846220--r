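---
title: "Modeling the cell cycle as a sequence of switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cell cycle as a sequence of switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctraj)
```

## The model

`cctraj` treats the cell cycle trajectory (CCT) of a proliferating cell
population as piecewise-linear motion in the log-space of *extensive*
quantities — amounts of transcripts, not concentrations — punctuated by
switches and a division event.

**Switching automaton.** The complete state is a pair `(x, s)`: a
position `x ∈ R^n` and a hidden intrinsic state `s` from a finite set.
Each state carries a growth vector `a_s`, so between events
`x(t) = x0 + a_s t` (allometric growth: power laws in the original
units). Every hyperplane is the zero set of `f(x) = b + <c, x>`; two
points lie on opposite sides exactly when the product of their
functionals is negative. Crossing a switch plane applies its state map
without moving the position; crossing the active division plane
translates the position by a vector `d` with strictly negative
components (`-log 2` per coordinate when each substance is split evenly
between daughters) and resets the intrinsic state.

**Why `m ≥ n`.** A cyclic trajectory must satisfy
`Σ λ_i a_i + d = 0` with nonnegative dwell times `λ_i`, i.e. `-d` must
lie in the convex cone spanned by the growth vectors of the visited
states. With fewer states than dimensions this fails for generic
vectors — each division would push the state out of the growth
subspace — so a stable cycle requires at least as many intrinsic states
as trajectory dimensions, `m ≥ n`.
`cone_feasibility()` decides membership by nonnegative least squares
(`pracma::lsqnonneg`) with a residual threshold of `1e-8` relative to
`|d|`, and returns a witness `λ` when feasible.

**The 2D cell cycle model.** In the plane of log aggregate S-phase and
G2/M expression, the intrinsic state is a pair of three-level triggers
(`2` = synthesis, `1` = passive decay, `0` = active degradation). Four
thresholds (`c_min` on the total, `S_max`, `M_max`, `M_e`) drive the
cycle `(0,0) → (2,2) → (1,2) → (1,1)` with division in `(1,1)`; with
one direction per visited state this gives 8 free parameters.
`build_2d_automaton()` reads the thresholds off five anchor points
(`x0, B', C, D, E`) and sets each state direction to the unit difference
quotient between consecutive anchors. The printed form of one rate
formula would give a positive `k1_S`, contradicting the stated
constraint `k1 < 0`; we consistently use (destination − source)/norm,
which satisfies `k0 < k1 < 0 < k2` and the visiting order.

**Kinetic model.** The lumped signals obey
`dS/dt = kt_S(t) − kd_S(t)·S` (same for `M`) with piecewise-constant
rates over the epochs `T1` (no synthesis, active degradation `kd_S`,
`kd_M`), `T1s` (synthesis on, base decay `kd_S2`, `kd_M2`), `T2s` (S
synthesis off, M synthesis boosted `p`-fold) and `Tm` (all synthesis
off), with cyclic closure `S(T) = S_f·S(0)`, `M(T) = M_f·M(0)`. Every
segment has the closed form `kt/kd + (x0 − kt/kd)·exp(−kd t)` (linear
when `kd = 0`), the closure fixes `S(0)`, `M(0)` analytically, and the
five epoch-boundary points follow by chaining. Within an epoch each
coordinate is monotone; the log-space segments are close to straight
lines except where one channel saturates.

## Identifiability and fitting

The ten boundary coordinates constrain only combinations of parameters:
the synthesis/decay ratios `kt/kd2`, the eight decay–duration products,
the drops `S_f`, `M_f` and the boost `p` — 13 raw combinations tied by
two trivial duration-ratio identities, hence **11 independent
combinations**. Since only 10 coordinates are measurable, one more
quantity (one of `p`, `T2s/T1s`, `Tm/T1s`) must be constrained, and
physical time is never identifiable from the trajectory alone. The
package fixes `T1` and `T1s` (conventionally to their pseudotime
fractions) and the ratio `Tm/T1s` (default `0.1`: mitosis an order of
magnitude faster than the S-phase induction epoch — the biologically
sensible direction of that constraint).

`fit_turning_points()` first inverts the closed forms channel by channel
(each decay segment gives a rate, each synthesis segment a saturation
level), which reproduces noise-free boundaries to machine precision,
then refines all ten free parameters jointly by quasi-Newton least
squares in log-parameter space (at most 500 iterations, parameter-change
tolerance `1e-8`; the residual is the unweighted sum of squared log
distances, the natural choice when all coordinates share the same
measurement scale).

**A conditioning caveat, quantified by the acceptance script.** With
mitosis ten-fold faster than `T1s`, the only segment that pins the base
decay rates in physical time is the mitosis decay, whose log drop
(`kd2·Tm ≈ 0.06` under the default parameters) is comparable to a
turning-point jitter of `0.01` per coordinate. Because the fit
interpolates 10 coordinates with 10 free parameters, the noise
propagates through convex nonlinearities: across jitter seeds the
recovered `kd2`-containing combinations are median-accurate to about 1%
but their *mean* is biased by several percent, and no aggregation
(arithmetic or geometric mean, bootstrap correction) removes this under
these conditions. This is an intrinsic property of the measurement
design, not of the optimizer: lengthening the mitosis epoch makes the
same estimator mean-accurate to well under 1%.

## The processing pipeline

`run_cct_pipeline()` reconstructs the CCT from a raw gene-by-cell count
matrix:

1. *Initial normalization* — scale each cell to the global median total,
   `ln(x+1)`, top variable genes (default 10,000, capped), PCA (default
   30 components), Euclidean kNN (default `k = 10`).
2. *Pooling* — sum each cell's raw counts with its neighbours' to
   compensate drop-out; pooled counts feed the trajectory fit, raw
   totals are kept as the progression signal.
3. *Principal circle* — a self-contained elastic polyline fitter
   minimizing mean squared point-to-node distance plus stretching
   (`λ Σ‖y_i − y_j‖²`, default `λ = 0.01`) and bending
   (`μ Σ‖y_{i−1} − 2y_i + y_{i+1}‖²`, default `μ = 0.1`) penalties.
   Both alternating steps decrease the energy, so fitting is monotone;
   nodes are initialized on an ellipse in the two leading PCs. An open
   curve is obtained by fitting a closed one with `q + 1` nodes,
   deleting the least-populated node and refitting the `q`-node path —
   the deletion opens the loop exactly where the data are sparsest
   (the division gap).
4. *Pseudotime* — each cell projects onto its nearest edge; pseudotime
   is the geodesic distance from the root in edge units (`[0, q−1]`
   open, `[0, q)` closed). The root and orientation are chosen so the
   per-node median of the initial totals increases along the cycle
   (brute-force over roots and directions), placing the origin at the
   division gap.
5. *Trajectory-based normalization* — global library-size scaling would
   erase the biological halving of totals at division, so instead each
   cell is scaled to the smoothed local median total at its pseudotime.
   The node partition that mixes pre- and post-division cells is
   detected as "anomalously wide" (IQR above 3× the median partition
   IQR), split at the antimode of its totals (two-cluster 1D k-means
   midpoint), and the two halves are reassigned to the neighbouring
   partitions; partition medians are then smoothed by a cyclic
   running mean (window 3 nodes) and interpolated linearly in
   pseudotime. Each column is multiplied by a single factor, so
   within-cell gene proportions are preserved, and the split's
   high/low median ratio estimates the division drop. Counts are then
   re-pooled on a kNN graph recomputed from the renormalized data and
   re-transformed.
6. *Curvature segmentation* — node coordinates are interpolated by
   natural cubic splines of pseudotime (cyclically padded for closed
   curves) and the curvature at node `i` is the Euclidean norm of the
   second-derivative vector; since nodes are approximately equispaced
   this is the unnormalized second derivative, with true Frenet
   normalization available via `normalize = TRUE`. Peaks are cyclic
   local maxima above 25% of the maximum, at most 5 — these mark the
   switches between transcriptional epochs and cut pseudotime into the
   segments `T1, T1s, T2s, Tm`.
7. *Scores, markers, dimensionality* — phase scores are mean `ln`-scale
   marker expression (log geometric mean of pseudocounts); epoch
   markers are ranked by in-vs-out mean log difference above a variance
   floor (top 20); `effective_rank()` counts leading singular values
   within a 10-fold conditioning bound.

## The synthetic generator

`generate_cct_counts()` emulates exactly the structure the framework
assumes: cells uniform in physical time along the analytic kinetic
cycle; four 50-gene epoch programs whose expected expression follows a
synthesize-during-epoch / decay-elsewhere law (so the population's path
in log space turns sharply at the epoch switches); 800 background genes
on a linearly rising cell-size trend; all components closing the cycle
with a division drop of `S_f = M_f = 1.8`, matching the empirically
observed 1.7–1.8 rather than the ideal 2; negative binomial sampling
(dispersion 0.1) with optional drop-out. The defaults (2,000 cells ×
1,000 genes, ~20.6 h cycle with `T2s/T1s = 1`, `Tm = T1s/10`, boost
`p = 2.5`) are the package's standing study conditions.

What the generator does *not* emulate: batch effects, doublets,
ambient RNA, splicing kinetics, non-cycling subpopulations, and
continuous (rather than switch-like) program changes. Passing the
recovery tests therefore shows the pipeline is correct under its own
model assumptions — rising totals, an abrupt division drop, and
piecewise-linear log dynamics — not that it is robust to every real
dataset.

## Numerical choices

- Crossing detection is the exact ray–hyperplane intersection
  `t* = −f(x0)/<c, a>`, accepted when `t* > 1e-12`; a plane is armed
  only when the trajectory is measurably off it (`|f| > 1e-9` on the
  plane's own scale), which prevents re-triggering the plane an event
  just landed on. Simultaneous crossings (non-general position) resolve
  to the smallest plane index with a warning.
- Divergence is declared at coordinate magnitude `1e6` (log units); a
  ray with no plane ahead and nonzero growth is likewise divergent, and
  a zero growth vector with no reachable plane stalls.
- Limit-cycle detection requires three consecutive post-division
  distances below `1e-8`, probing division periods up to 4. The birth
  hyperplane is derived (division plane translated by `d`), never
  stored.
- Natural logarithms everywhere; the division vector defaults to the
  observed `x0 − E` (equal to `(−log S_f, −log M_f)`) and to `−log 2`
  in idealized settings.
- Laplace score noise (default scale 0.05 log units) is sampled by
  inverse CDF so fixed seeds give identical clouds.

## Problem sizes

The test suite runs the full pipeline on 2,000 cells × 1,000 genes
(about 20 s), the analytic-vs-ODE and closure sweeps on 1,000 random
parameter draws each, the cone property on 1,000 random specs plus 100
grid-search cross-checks, and the recovery study on 100 jitter seeds;
module tests use 300–600 cell fixtures. `scripts/acceptance.R` repeats
these measurements from scratch under a single command-line seed in
about 15 s.

## Known limitations

- The elastic fitter uses nearest-node (not nearest-segment)
  partitioning during optimization, like classical elastic-map
  algorithms; projections are segment-accurate afterwards.
- Curvature peak positions on noisy data are accurate to roughly one
  node; with 50 nodes that is ±2% of the cycle.
- The automatic root can sit a node or two off the division gap when
  the totals signal is smooth; a sharp planted drop (as in real cycling
  data) anchors it reliably.
- The doubling-time regression is ordinary least squares with explicit,
  user-supplied outlier exclusion (plus an optional studentized-residual
  flag); it does not curate doubling times from external databases.
- Reproducing the reference analyses on real data (CHLA9, the cell-line
  panel) requires the external downloads described in
  `inst/scripts/external_data_workflow.R`.
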