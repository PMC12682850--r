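# rootshift

Drought ends; water returns. Which rice genotypes pour their recovery into
new crown roots, and which keep growing shoots as if nothing happened?
`rootshift` is an R package for analysing this shoot-versus-root investment
during drought recovery, written for plant phenomics and quantitative
genetics groups working with field and glasshouse trials of rice
(*Oryza sativa*).

It implements four connected analyses:

* **Growth rates** — relative growth rate from shoot dry weights,
  RGR = (ln SDW₂ − ln SDW₁)/Δt, and per-compartment rates from longitudinal
  leaf-length and crown-root-number records, with plant → plot → line
  averaging and additive block adjustment.
* **Water Recovery Index (WRI)** — line-level shoot and root rates are
  rescaled to [1, 100] per treatment and compartment, combined into the
  shoot-to-root growth-rate ratio SRGR = ln(rescaled shootGR / rescaled
  rootGR), and differenced across treatments:
  WRI = SRGR(drought) − SRGR(well-watered). More negative = stronger
  root-biased recovery ("conservative" strategy).
* **GWAS peak co-location** — single-linkage clustering of filtered
  per-season association hits within a 100-kb window, retained when peaks
  recur across seasons, plus candidate-gene extraction in ±100-kb flanks
  from a GFF3 or CSV annotation.
* **Root architecture** — partitioning of scanned root systems into S-type
  (≤ 0.15 mm), L-type (0.15–0.37 mm) and axial (> 0.37 mm) diameter
  classes, link analysis estimating mean S-type lateral-root length from
  tip counts, lateral-order assignment, and longevity-score aggregation.

Synthetic-data generators emulate the underlying study designs (a
20-genotype recovery field trial, three-season GWAS summary tables,
glasshouse root systems whose architecture shifts under drought and
reverses after re-watering) with planted, recoverable truth, so the whole
pipeline is testable without field data.

## Worked example

Simulate the recovery field design and rank genotypes by WRI. Genotype
strategies are planted on a gradient from 0 (conservative) to 1
(less-conservative):

```r
library(rootshift)

cfg <- field_sim_config()                       # 20 genotypes x 2 treatments x 4 plots x 2 plants
sim <- gen_field_phenotypes(cfg, seed = 101)    # 2560 observations + truth table
wri <- compute_wri_table(sim$observations, cfg$schedule, window = c("M2", "M3"))
head(wri, 4)
#>   genotype_id srgr_drought srgr_well_watered   wri strategy_rank strategy
#> 1 G01                -4.36           -0.117  -4.25             1 conservative
#> 2 G03                -2.26            0.0590 -2.32             2 conservative
#> 3 G02                -1.54            0.0209 -1.56             3 conservative
#> 4 G04                -1.48            0.0307 -1.51             4 conservative
```

G01 carries planted strategy 0: under drought its shoots grew at half speed
while crown-root production jumped 1.5× after re-watering, so its drought
SRGR is strongly negative (root-dominated) while its well-watered SRGR sits
near zero — the most negative WRI in the panel. At the other end, G20
(strategy 1, no treatment contrast) tops the ranking with WRI = 3.68.

Co-locating planted GWAS peaks across seasons:

```r
peaks <- tibble::tibble(chrom = c("3", "8"), pos = c(1.2e7, 2.4e7),
                        seasons = c("2017,2018", "2017,2019"), neglog10p = 5)
gw <- gen_gwas_tables(gwas_sim_config(peaks = peaks,
                                      background_max_neglog10p = 3), seed = 101)
find_colocations(filter_hits(gw$hits), window_bp = 100000)
#>   cluster_id chrom    start      end n_hits n_seasons seasons
#> 1 coloc_001  3     12007501 12024564      2         2 2017,2018
#> 2 coloc_002  8     24003689 24004631      2         2 2017,2019
```

Both planted peaks are recovered, none invented. Root-system summaries show
the drought shift towards L-type laterals:

```r
sys <- gen_root_system(root_sim_config(), "drought", seed = 101)
summarize_root_types(sys$segments)[, c("prop_S", "prop_L", "prop_axial")]
#>   prop_S prop_L prop_axial
#> 1  0.273  0.444      0.284
link_analysis(sys$segments)[, c("external_links", "internal_links", "mean_s_lr_length")]
#>   external_links internal_links mean_s_lr_length
#> 1            110             35             7.07
```

Under drought the S-type length share drops to 0.27 (well-watered systems
from the same configuration sit near 0.5), and the link analysis recovers
the mean S-lateral length (true distribution mean 7.14 mm) from tip counts.
`run_pipeline()` chains these stages and writes CSV outputs, a run log and
a text summary into a directory, reproducibly by seed.

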