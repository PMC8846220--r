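# cctraj — cell cycle trajectories as a sequence of switches

Proliferating cells traverse a closed loop in gene-expression space: total
transcript content rises through interphase and halves abruptly at
cytokinesis, while the transcriptional program turns at a small number of
sharp switch points. `cctraj` models this cell cycle trajectory (CCT) at
three levels and reconstructs it from raw single-cell RNA-seq counts:

1. **Hybrid switching automaton.** The cell is a point `x ∈ R^n` of
   log-amounts of extensive quantities, moving linearly (`x = x0 + a_s t`)
   with a growth vector `a_s` set by a hidden intrinsic state `s`.
   Crossing a switch hyperplane `f(x) = b + <c, x> = 0` changes `s`;
   crossing the division plane translates the position by a vector `d`
   with negative components (ideally all `-log 2`) and resets the state.
   A stable cycle requires nonnegative dwell times `λ_i` with
   `Σ λ_i a_i + d = 0`, i.e. `-d` inside the convex cone of the growth
   vectors — hence the number of intrinsic states `m` is at least the
   trajectory dimensionality `n` (`cone_feasibility()` tests this as an
   NNLS feasibility problem).
2. **Analytic kinetic model.** Two lumped signals, `S` (S-phase program)
   and `M` (G2/M program), obey `dS/dt = k_t(t) − k_d(t) S` with
   piecewise-constant rates over four transcriptional epochs
   `T1 → T1s → T2s → Tm` and cyclic closure `S(T) = S_f·S(0)`,
   `M(T) = M_f·M(0)`. The model is solved in closed form, its epoch
   boundaries are fitted to observed trajectory turning points, and
   exactly 11 independent parameter combinations are identifiable.
3. **scRNA-seq pipeline.** kNN pooling of raw counts, trajectory-based
   library-size normalization (each cell scaled to the smoothed local
   median total at its pseudotime, preserving the rising-then-halving
   totals), elastic principal circle fitting, pseudotime rooted at the
   division gap, curvature-peak segmentation into epochs, phase scores,
   epoch markers, and effective-rank dimensionality. The principal-circle
   length in the scaled score plane (`LP`) predicts the population
   doubling time by linear regression.

A synthetic generator (`generate_cct_counts()`) produces count matrices
with known ground truth (phase, epoch, division drop) so every stage is
testable without downloads.

## Worked example

```r
library(cctraj)

# synthetic cycling population: 1000 cells x 600 genes, division drop 1.8
sim <- generate_cct_counts(synth_config(n_cells = 1000, n_genes = 600,
                                        seed = 1))
res <- run_cct_pipeline(sim$counts, q = 40, seed = 0)

cor(as.numeric(res$pseudotime), sim$truth$phase, method = "spearman")
#> 0.963        # pseudotime tracks the true cycle phase
res$normalization$split$drop_ratio
#> 1.67         # recovered division drop (1.8 planted)

# fit the kinetic model to jittered trajectory turning points
pr  <- default_kinetic_params()
tp  <- generate_turning_points(pr, jitter = 0.01, seed = 3)
fit <- fit_turning_points(tp, T1 = pr$T1, T1s = pr$T1s)
fit
#> Kinetic cell cycle model parameters
#>   S: kt = 1.873, kd (post-div) = 0.1492, kd2 (base) = 0.07753, drop S_f = 1.82
#>   M: kt = 1.286, kd (post-div) = 0.1999, kd2 (base) = 0.05856, drop M_f = 1.82, boost p = 1.96
#>   epochs (h): T1 = 8, T1s = 6, T2s = 7.92, Tm = 0.6 (T = 22.52)
```

The pseudotime correlation says the closed curve ordered the cells
correctly around the cycle; the drop ratio is the totals ratio between the
pre- and post-division sub-partitions found by the normalization split;
the fitted parameters recover the generating kinetics up to the
identifiable combinations (physical time is fixed only through the `T1`,
`T1s`, `Tm/T1s` constraints).

A command-line wrapper for the main operations is installed at
`inst/scripts/cct.R`, and `inst/scripts/external_data_workflow.R`
documents how to apply the pipeline and the doubling-time regression to
externally downloaded datasets.

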