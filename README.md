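# ecominima

Presence-only species distribution modelling centred on **ecological
minimums**: the combinations of environmental conditions that vary least
across a species' occurrence locations and therefore behave like limiting
requirements. The package implements the partitioned Mahalanobis distance
framework for landscape-scale habitat modelling — developed for
range-wide analyses of greater sage-grouse lek data — together with the
evaluation toolkit and circuit-theory connectivity modelling that
accompany it, and a synthetic-landscape generator that makes the entire
pipeline testable end to end without any external GIS data.

## The model

For an environment vector **x** of *p* variables, the Mahalanobis
distance from the occurrence mean decomposes along the principal
components of the occurrence correlation matrix *R* = *E*Λ*E*ᵀ:

    D² = Σⱼ cⱼ,   cⱼ = (eⱼᵀz)² / λⱼ,   z = diag(σ̂)⁻¹ (x − μ̂)

The *p* partitions are orthogonal and additive. Low-eigenvalue partitions
(λ ≤ 1) describe conditions the species holds nearly constant wherever it
occurs — the ecological minimums. Mapping uses the minimum-variance tail
D²(k) = Σ_{j≥k} cⱼ and rescales it to a habitat similarity index

    HSI = Pr(χ²_{p−k+1} > D²(k)) ∈ [0, 1]

with HSI = 1 exactly at the occurrence mean. Fitting is
bootstrap-averaged (per-population caps, eigenvector sign correction),
evaluation uses presence–background ROC/AUC, median HSI, dose-response
curves with a lek-coverage threshold, variable importance and group
summaries, and connectivity converts the HSI surface to resistance
(r = 1/HSI, clamped to [1, 10⁵]) and accumulates all-to-one circuit
solves with lek-count-weighted sources into a cumulative current map.

## Worked example

```r
library(ecominima)
res <- run_pipeline(demo_config(seed = 7), out_dir = "demo-out")
res$model
#> <eco_partition_model> p = 10 variables, n = 350 occurrences
#>   bootstrap: 1000 iterations, population cap 25, seed 80063; orthogonality deviation 1.75e-02
#>   eigenvalues: 2.96 1.88 1.54 1.24 1 0.545 0.464 0.362 0.00587 0.00417
#>   boundary partition k = 9 (tail mode, chi-square df = 2)

round(res$evaluation[c("auc_evaluation", "median_hsi_evaluation",
                       "median_hsi_historic", "hsi_threshold")], 3)
#>   auc_evaluation median_hsi_evaluation median_hsi_historic hsi_threshold
#> 1          0.848                 0.441                   0         0.103
```

The demo landscape plants two low-variance niche directions (SD 0.1
against 1.0 elsewhere) and the fitted eigenvalue ladder recovers them:
the two deepest partitions have eigenvalues ≈ 0.005 and the selected tail
(k = 9, two partitions) is exactly the planted minimum subspace. The
evaluation row reads: held-out leks are ranked above random landscape
cells 84.8% of the time; the median held-out lek scores HSI 0.44 while
historic (extirpated) locations score ~0; and 90% of leks sit at or above
HSI 0.10, the dose-response threshold. `autoplot(res$hsi)`,
`autoplot(res$dose$var01)`, `plot_eigenvalue_ladder(res$model)` and
`autoplot(res$current$raster, trans = "log10")` draw the habitat map,
dose-response curve, eigenvalue ladder and cumulative current map;
`tidy()` / `glance()` give broom-style model summaries.

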