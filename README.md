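# plsDeltaNet

Differential multi-omics association networks via partial least squares and
delta eigenvector centrality.

## What this is for

Patients with major depressive disorder and a lifetime history of attempted
suicide respond differently to antidepressants than patients without such a
history. A way to look for the biology behind that difference is to build an
association network linking genetic variants (SNVs), plasma metabolites and
the binary treatment response **separately within each stratum**, and then
ask which features change their network importance most between strata.
plsDeltaNet implements that analysis as a tested, reusable pipeline for any
two-stratum genomic–metabolomic cohort:

1. **SNV screen** — genotypic (2-df) chi-square association of each variant
   with the stratum flag, nominal p ≤ 0.05, followed by greedy linkage-
   disequilibrium pruning (r² ≤ 0.8 within chromosomes).
2. **Metabolite preprocessing** — exclusion at ≥ 10% missingness,
   K-nearest-neighbour imputation, per-metabolite maximum-likelihood
   Yeo–Johnson transform, centering and unit-variance scaling.
3. **Network construction per stratum** — for each pair of feature blocks a
   sparse-capable NIPALS PLS fit; associations reconstructed from the
   orthogonal latent scores as
   `s_ij = Σ_h cor(x_i, t_h) · cor(y_j, t_h)`,
   an edge kept iff `|s| > 0.1` and `p < 0.05` (correlation t-test, both
   strict; optional Benjamini–Hochberg correction); weighted Louvain
   communities; eigenvector centrality max-normalized to 1.
4. **Differential comparison** — delta centrality `Δ = |c_A − c_B| ∈ [0, 1]`
   per feature (absent features carry centrality 0), ranked; edge-level
   only-A / only-B / shared report.
5. **Synthetic cohorts** — a generator with planted group-specific
   SNV→metabolite effects, stratum-specific allele frequencies, a
   metabolite-linked response, and a ground-truth registry for scoring
   recovery end to end.

## Worked example

Simulate the standard benchmark cohort (two strata of 400 samples, 10 SNVs,
40 metabolites in five analyte-class blocks, four effects planted on one hub
SNV in the "attempt" stratum only), run the stratified analysis, and score
it against the planted truth:

```r
library(plsDeltaNet)

cohort <- generateCohort(benchmarkConfig(seed = 42))
cohort$genotypes
#> GenotypeMatrix: 800 samples x 10 SNVs
#>   missing dosages: 0

prep <- preprocessMetabolites(cohort$metabolites)
nets <- stratifiedNetworks(dosages(cohort$genotypes), prep$matrix,
                           cohort$phenotypes$response,
                           cohort$phenotypes$attempt,
                           networkConfig(bhCorrect = TRUE, seed = 42))
nets$netA
#> OmicsNetwork: 7 nodes, 5 edges (n = 400 samples)
#>   blocks: metabolite=4, outcome=1, snv=2
#>   communities: 2
nets$netB
#> OmicsNetwork: 0 nodes, 0 edges (n = 400 samples)

head(nets$delta, 5)
#>   feature      block centralityA centralityB     delta rank
#> 1  snv001        snv   1.0000000           0 1.0000000    1
#> 2  met025 metabolite   0.5584081           0 0.5584081    2
#> 3  met001 metabolite   0.4933826           0 0.4933826    3
#> 4  met017 metabolite   0.4912046           0 0.4912046    4
#> 5  met009 metabolite   0.4510787           0 0.4510787    5

scoreRecovery(nets$delta, nets$netA, nets$netB, cohort$truth,
              topK = 3)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0
```

The hub SNV is connected to its four planted metabolites only in the attempt
stratum's network, so its delta centrality is 1 (rank 1), and all four
planted edges are recovered with no false group-specific calls.

For file-based workflows, `simulateToFiles()` writes a cohort as
VCFv4.2 + CSV + JSON truth, and `runPipeline(runConfig(...))` executes the
whole analysis from those files, writing GraphML networks, TSV edge lists
and delta tables, and a manifest JSON with reproducible MD5 checksums.
`readRunConfig()` loads thresholds from a YAML file.

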