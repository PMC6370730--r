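# skfuse

Patient subtype discovery from multiple expression views by **similarity
kernel fusion**: per-view patient similarity kernels, an α-anchored
cross-diffusion over k-nearest-neighbour graphs that merges them into one
kernel, normalized-cut spectral clustering of the fused kernel, and
survival-based evaluation of the resulting subtypes.

## Who it is for

Anyone with two or more numeric patient × feature matrices (e.g. gene,
miRNA and isoform expression from the same tumour cohort) plus optional
right-censored clinical follow-up, who wants reproducible cluster labels
and a quantitative measure of how well those clusters separate survival.

## The method

For each view, features are z-scored, squared Euclidean distances
`D_ij = (e_i − e_j)ᵀ(e_i − e_j)` are converted to similarities with a
locally scaled exponential kernel `K_ij = exp(−D_ij / (μ ε_ij))`, and two
operators are built: a column-stochastic transition kernel `P` and a
row-stochastic sparse kernel `S` supported on each patient's k nearest
neighbours. With `L` views, fusion iterates

    P_l ← α · S_l (mean of the other views' P) S_lᵀ + (1 − α) · (mean of the other views' initial P)

with column re-normalization, averages the per-view states into `K_com`,
and multiplies by a mutual-kNN mask (1 reciprocated / 0.5 one-way / 0
neither) before symmetrizing into the fused kernel `K*`. Subtypes are the
k-means clusters of the row-normalized bottom eigenvectors of
`L⁺ = I − D^{−1/2} K* D^{−1/2}`, and each subtyping is scored with the
C-sample log-rank test (reported as −log₁₀ p) and Kaplan–Meier curves.

See `vignette("kernel-fusion-subtyping")` for the full account of the
model, parameter defaults, numerical choices, and limitations.

## Worked example

Everything below runs offline on a simulated 3-view cohort with three
planted subtypes (30 patients each) whose hazard rates differ threefold.

```r
library(skfuse)

sim <- simulate_cohort(seed = 42)   # cohort + planted labels
sim$cohort
#> <cohort> 90 patients, 3 views (gene, mirna, isoform), with survival

fit <- skf(sim$cohort, alpha = 0.5) # fuse the three views
fit
#> <skf_fit> 90 patients, 3 views (gene, mirna, isoform)
#>   alpha = 0.5, k = 9, mu = 0.5; 12 iteration(s), converged

asg <- spectral_cluster(fit$fused, C = 3, seed = 42)
glance(asg)
#> # A tibble: 1 × 4
#>   n_patients     C min_cluster_size max_cluster_size
#>        <int> <int>            <int>            <int>
#> 1         90     3               30               30

logrank_test(sim$cohort$survival, asg)
#> Log-rank test: chi-square = 43.58 on 2 df, p = 3.448e-10
#>   group sizes: 30, 30, 30
```

The three recovered subtypes match the planted ones exactly (adjusted Rand
index 1), and their survival profiles separate decisively (p ≈ 3.4 × 10⁻¹⁰):
the planted hazards 0.05 / 0.15 / 0.45 are what the log-rank test detects.
Scanning the number of clusters makes the selection explicit:

```r
scan_clusters(fit$fused, sim$cohort$survival, C_range = 2:6, seed = 42)
#> # A tibble: 5 × 5
#>       C chi_square    df  p_value neg_log10_p
#>   <int>      <dbl> <int>    <dbl>       <dbl>
#> 1     2       32.1     1 1.48e- 8        7.83
#> 2     3       43.6     2 3.45e-10        9.46
#> 3     4       51.2     3 4.52e-11       10.3
#> 4     5       52.0     4 1.39e-10        9.86
#> 5     6       52.0     5 5.27e-10        9.28
```

`autoplot()` methods plot Kaplan–Meier curves (`km_curves()`), scan tables,
and α sweeps (`alpha_scan()`, default grid 0, 0.1, …, 1); `tidy()` and
`glance()` return tibble summaries of fits and tests.

File-based cohorts run through a single config (see `?run_pipeline` for the
YAML schema), which writes the fused kernel, assignments, scan table, KM
curve data, and a run manifest — bit-identical on rerun:

```r
run_pipeline("config.yaml")
```

or from a shell via the thin CLI (`inst/cli/skfuse.R`) with verbs `run`,
`alpha-scan`, `simulate`, and `version`.

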