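# declust

Reference-free deconvolution and cancer-intrinsic subtyping of bulk tumor
transcriptomes.

Bulk tumor expression mixes cancer cells with immune and stromal
infiltrate, so molecular subtypes called on bulk profiles confound
cancer-cell biology with microenvironment composition, and reference-based
deconvolution needs compartment profiles that rarely exist for the tissue
at hand. `declust` jointly estimates, from a single genes × samples
log-expression matrix and nothing else but immune/stromal marker gene
lists:

* per-sample compartment fractions `(f_cancer, f_immune, f_stromal)` on the
  unit simplex (tumor purity is `f_cancer`),
* a cancer cell-intrinsic subtype label per sample, and
* cohort-level reference expression profiles for the immune and stromal
  compartments and each of the K cancer subtypes.

## Model

Mixing is linear on the natural expression scale and fit on the log scale.
For gene *i*, sample *j* with subtype assignment *s(j)*:

```
exp(o_ij) ≈ exp(E_i^subtype_s(j)) · f_j^cancer
          + exp(E_i^immune)       · f_j^immune
          + exp(E_i^stromal)      · f_j^stromal
```

All unknowns minimize `Σ_ij (o_ij − log reconstruction_ij)²` by a two-layer
block-coordinate scheme: marker-based fraction initialization with a 10×10
grid search for the two marker-to-fraction scaling constants; an inner
layer alternating per-gene profile estimation (box-constrained L-BFGS-B,
analytic gradients) with exhaustive per-sample subtype reassignment; an
outer layer alternating the inner layer with per-sample fraction
optimization, closed by a joint quasi-Newton refinement of all continuous
parameters. The number of subtypes is chosen from the BIC curve
`log(MSE)·n + log(n)·K` by combining its minimum and elbow. See the
methods vignette (`vignettes/declust-methods.Rmd`) for assumptions,
parameter meanings, and numerical details.

The package also bundles the benchmark machinery around the method: a
synthetic bulk-mixture simulator with full ground truth (configurable
profile correlation structure, subtype-conditional simplex fractions,
log-normal or negative-binomial noise), two comparator pipelines (plain
K-means on bulk; reference-subtraction + quantile normalization + K-means),
and recovery metrics (fraction/profile correlations, best-permutation
clustering accuracy with adjusted Rand index).

## Worked example

```r
library(declust)

cfg <- simulation_config(n_genes = 400, n_samples = 60, n_subtypes = 3,
                         noise_level = 0.3, seed = 42)
sim <- simulate_dataset(cfg)                       # mixtures + ground truth
fit <- run_declust(sim$observed, sim$markers, n_subtypes = 3,
                   declust_control(seed = 42))
print(fit)
#> declust fit: 400 genes, 60 samples, K = 3
#>   objective (sum) = 1979.96, mean = 0.0824981, converged = FALSE
#>   subtype sizes: 36, 16, 8

evaluate_recovery(sim, fit)
#> Recovery: fractions 0.986 | clustering 1.000 (ARI 1.000) | profiles 0.902

round(head(fit$fractions, 3), 3)
#>            cancer immune stromal
#> sample_001  0.673  0.215   0.112
#> sample_002  0.792  0.093   0.115
#> sample_003  0.487  0.222   0.291
```

The fit recovered every sample's subtype (clustering accuracy 1.0 up to
label permutation), per-sample fractions correlating 0.986 with the
simulated truth, and compartment profiles correlating 0.902 with the true
profiles, at log-noise sd 0.3. (`converged = FALSE` here only means the
outer loop used its full iteration cap before the relative-change tolerance
was met; the trailing iterations change the objective by a few percent.)

On real data: read the matrix with
`read_expression_matrix(path, declared_scale = "log2")` (or `"linear"` /
`"natural"`), drop flat genes with `filter_low_variance_genes()` (sd < 0.5,
log scale), pass marker lists via `read_marker_sets()` or use the bundled
`default_markers()` panels (HGNC symbols), and choose K with
`declust_select_k()`. Results are written/read by
`write_declust_result()` / `read_declust_result()`. A command-line front
end with `fit`, `select-k`, `simulate`, `evaluate`, and `baseline`
subcommands is installed at `inst/cli/declust.R`.

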