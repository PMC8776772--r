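# coarsetraits

Coarse-grained proteomic traits of microbial taxa from metaproteomes — with
a built-in ground-truth simulator for knowing when to trust them.

## What problem this solves

Peptide-level metaproteomics can, in principle, measure how each taxon in a
mixed community allocates its proteome: what fraction of a diatom's protein
mass is ribosomes, how much of SAR11's proteome is expressed constitutively.
In practice the inference is obstructed by peptides shared between taxa,
database-dependent normalization, size-fractionated sampling that splits
each organism across filters (3.0 / 0.8 / 0.1 µm), and the intensity bias of
data-dependent acquisition (DDA). `coarsetraits` is for computational
microbial ecologists and proteomics methodologists who want both the
inference chain and a way to quantify its biases on synthetic communities
where the truth is known.

The package implements:

* **Proteomic mass fractions** — for taxon *T* and pool *P*
  (ribosomal / photosynthetic),
  φ̂ = Σ intensities of peptides unique to *T*∩*P* ÷ Σ intensities of
  peptides unique to *T*, after presence filtering across replicate
  injections, per-injection sum (or TIC) normalization, and injection
  averaging (`mass_fraction()`, `pool_fraction_table()`).
* **Filter-weighted combination** — per-filter estimates combined with
  weights *w_f = n_f / Σ n_g* from per-filter peptide observation counts
  (`filter_weights()`, `combine_across_filters()`), plus protein-mass
  weighting for taxon relative abundance (`taxon_relative_abundance()`).
* **Regulatory-cost proxy** — peptides classified environment-dependent vs
  -independent by their coefficient of variation across timepoints against
  a cutoff calibrated on replicate cultures (mean across conditions of the
  third quartile of protein-level CVs; `derive_cutoff()`,
  `classify_peptides()`, `environment_independent_fraction()`).
* **Synthetic communities + DDA simulator** — multi-taxon proteomes with
  configurable pool fractions, inter-taxon sequence sharing, environmental
  modulation, filter leakage and injection noise
  (`simulate_community()`), acquired by a top-N / dynamic-exclusion
  acquisition loop (`simulate_dda_run()`), and scored against truth
  (`assess_bias()`, `bias_sweep()`, `support_threshold()`).
* **Cofragmentation risk scores** — expected number of co-isolated
  peptides given an isolation window, peak width and predicted retention
  times (`cofragmentation_score()`, `rt_model()`).

## Worked example

Simulate a 3-taxon community (ribosomal/photosynthetic/other pools at
0.20/0.15/0.65 per taxon), acquire one DDA injection per timepoint × filter,
and recover the coarse-grained traits:

```r
library(coarsetraits)

cfg <- community_config(n_taxa = 3, n_proteins_per_pool = 20,
                        shared_sequence_fraction = 0, seed = 1)
sim <- simulate_community(cfg)
map <- build_peptide_map(sim$proteins)

set.seed(1)
params <- dda_params()   # 125-min gradient, top-10, 0.5-min exclusion
obs <- list()
for (tp in 1:4) for (f in c("3.0", "0.8", "0.1")) {
  feats <- generate_features(map, sim$truth, tp, f, params)
  run <- simulate_dda_run(feats, params)
  run <- run[run$identified, c("peptide", "intensity")]
  run$timepoint <- tp; run$filter <- f; run$injection <- 1L
  obs[[length(obs) + 1L]] <- run
}
observed <- dplyr::bind_rows(obs)

fractions <- pool_fraction_table(observed, map)
dplyr::filter(fractions, filter == "combined", timepoint == 1)
#> # A tibble: 6 × 7
#>   taxon  pool           timepoint filter   value n_peptides weight
#>   <chr>  <chr>              <int> <chr>    <dbl>      <int>  <dbl>
#> 1 taxon1 ribosomal              1 combined 0.153       2113     NA
#> 2 taxon1 photosynthetic         1 combined 0.189       2083     NA
#> 3 taxon2 ribosomal              1 combined 0.245       1950     NA
#> 4 taxon2 photosynthetic         1 combined 0.213       1987     NA
#> 5 taxon3 ribosomal              1 combined 0.170       1785     NA
#> 6 taxon3 photosynthetic         1 combined 0.116       2025     NA
```

Each `value` is the filter-combined mass fraction of that pool in that
taxon's proteome at week 1, supported by `n_peptides` taxon-and-pool-unique
peptide observations. The estimates track the *realized* ground truth —
which environmental modulation moves away from the configured 0.20/0.15 —
almost exactly (e.g. taxon1 ribosomal truth 0.153, inferred 0.153; taxon3
photosynthetic truth 0.116, inferred 0.116): with ample unique peptides,
DDA sampling bias is negligible for these ratios.

Classify constitutive vs regulated proteome mass against a
replicate-culture-calibrated CV cutoff:

```r
cultures <- simulate_replicate_cultures(4, 3, 800,
  cv_profile = list(meanlog = log(0.15), sdlog = 0.4), seed = 1)
cutoff <- derive_cutoff(cultures)
round(cutoff$cutoff, 4)
#> [1] 0.1894

series <- taxon_peptide_series(observed, map)
classified <- classify_peptides(peptide_cv_table(series), cutoff)
environment_independent_fraction(classified)
#> # A tibble: 3 × 4
#>   taxon  fraction n_independent n_dependent
#>   <chr>     <dbl>         <int>       <int>
#> 1 taxon1    0.220           630        1468
#> 2 taxon2    0.513          1162         816
#> 3 taxon3    0.376           988        1029
```

`fraction` is the share of each taxon's proteome mass carried by peptides
whose week-to-week CV stays below the cutoff — the environment-independent
(low regulatory cost) proteome fraction. Differences between the taxa here
reflect their randomly realized mixes of modulated proteins.

`run_pipeline(config, out_dir)` performs all of the above (plus bias and
cofragmentation reports) and writes TSV outputs with a JSON manifest;
`inst/scripts/coarsetraits-cli.R` exposes the same stages as shell
subcommands (`simulate-community`, `quantify`, `traits`, `cofrag`,
`run-all`).

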