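# panoric

Positional pan-genome analysis along the oriC→terC replication axis of
circular bacterial chromosomes.

## What it does, and for whom

Bacterial chromosomes replicate bidirectionally from a single origin
(*oriC*) to a terminus (*terC*); genes near the origin are replicated early
and enjoy a dosage advantage in growing cells.  panoric is for comparative
genomicists who want to know whether **gene conservation** — and the
placement of prophages and genomic islands — is structured along that axis
in a cohort of closed genomes.

For a gene of a focal strain, its **ortholog score** is the number of
*other* strains in the cohort carrying at least one ortholog (0 =
strain-specific, *n* − 1 = core, for *n* strains).  Per strain, panoric
regresses the mean ortholog score of sliding 20-gene windows on the
normalized circular distance *d* ∈ [0, 1] from *oriC*:

    E[ s̄_w ] = a + β · d_w

A negative β means conserved genes cluster near the origin.  Because
adjacent windows share 19 genes, the slope p-value uses a Newey–West (HAC)
variance rather than the naive OLS one.  Around this core fit the package
provides:

* **Pan-genome classification** (`read_proteinortho()`,
  `classify_families()`): core / soft-core (≥ ⌈0.95 · n⌉ strains) /
  accessory, with paralog and algebraic-connectivity (≥ 0.9) filters, and a
  one-strain-per-genus robustness reduction.
* **Origin calling** (`call_oric()`): intergenic DnaA-box clusters
  (TTATCCACA, TGTTTCACG, TGTGGATAT; 1 then 2 mismatches) ranked by
  proximity to the detrended cumulative G−C disparity extremum, local GC
  deficit and parAB proximity; ambiguous calls are excluded downstream.
* **Cohort statistics** (`slope_population()`, `segment_analysis()`,
  `thirds_region_analysis()`): QQ comparison of slopes to a normal
  distribution, eight-segment enrichment with strain-blocked ANOVA + Tukey
  HSD (segment 1 centered on *oriC*), and phage/island counts and DNA
  proportions across chromosome thirds of increasing distance from *oriC*.
* **A synthetic-cohort simulator** (`simulate_cohort()`,
  `write_fixture_set()`) that plants a conservation gradient, replichore GC
  skew, DnaA boxes, parAB genes and phage/island regions with known truth,
  so the whole pipeline is testable without downloads.
* **Orchestration** (`run_pipeline()`, `summarize_cohort()`, a YAML config,
  and a thin CLI at `inst/scripts/panoric`).

## Worked example

```r
library(panoric)

cfg <- sim_config(n_strains = 10, n_families = 700, genes_per_strain = 400,
                  genome_length = 8e5, positional_bias_beta = -4, seed = 42)
sim <- simulate_cohort(cfg)

classify_families(sim$pangenome)
#> Family classification for 10 strains (soft-core threshold: 10 strains)
#>   families: 689 | core: 315 | soft-core: 315 | core, no paralogs: 304 | + connectivity >= 0.9: 188

s  <- sim$strains[1]
oc <- call_oric(sim$sequences[[s]], sim$catalogs[[s]])
oc
#> oriC called at 548000 bp (of 800000): 14 DnaA boxes, 500 bp from disparity min

scores <- ortholog_scores(sim$pangenome, s, annotation = sim$catalogs[[s]])
frame  <- chromosome_frame(s, cfg$genome_length, oc$oric, scores)
fit    <- fit_conservation_gradient(window_series(frame))
fit
#> Conservation gradient [strain01]: slope -4.015 (HAC p = 9.79e-07, significant at 0.05), intercept 9.49, R^2 0.752
```

The call lands on the planted origin (truth: 548,000 bp — the 14 box hits
are the 6 planted 9-mers counted on both strands plus ambient matches), and
the fitted slope −4.0 recovers the planted β = −4: conserved genes were
placed preferentially near *oriC* and the window regression detects it.
Across the cohort:

```r
fits <- lapply(sim$strains, function(st) {
  sc <- ortholog_scores(sim$pangenome, st, annotation = sim$catalogs[[st]])
  fr <- chromosome_frame(st, cfg$genome_length,
                         call_oric(sim$sequences[[st]], sim$catalogs[[st]])$oric, sc)
  fit_conservation_gradient(window_series(fr))
})
slope_population(fits)
#> Slope population: 10 strains, 10 negative (10 significant), 0 positive (0 significant)
#>   mean -3.904, sd 0.416; 10/10 QQ points within the 0.05 KS band
```

A full end-to-end run (`run_pipeline()`) writes provenance-headed TSVs —
family classification, per-strain oriC calls and gradient fits, the slope
QQ table, segment and thirds summaries with Tukey tables — plus a run log.

## The methods vignette

`vignettes/positional-pangenome.Rmd` documents the statistical choices in
detail: why slope inference is HAC, why the segment/thirds ANOVAs block on
strain, how the origin-calling criteria are normalized and weighted, how
the simulator's rank-matching placement is calibrated so the realized
gradient equals the requested β, and what the synthetic cohorts do and do
not emulate about real genomes.
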