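# pollenscape

Two-generation landscape genetics of pollen-mediated gene flow in
clonal, self-incompatible, bumblebee-pollinated forest herbs.

Forest herbs such as *Polygonatum multiflorum* persist in small forest
patches scattered through agricultural landscapes. They grow clonally in
shoot clusters, are strictly outcrossing, and rely on trapline-foraging
bumblebees to move their pollen — within a patch and, when a forager's
route spans several patches, between them. `pollenscape` implements the
full analysis chain for studies that genotype both generations
(adult shoot clusters and the offspring germinated from the berries of
selected "pollen receptor" plants) at microsatellite loci:

1. **Genotype QC** — multilocus genotype (MLG) detection, clone
   deduplication with receptor priority, clonality-by-cluster-size
   statistics, mother–offspring mismatch resolution.
2. **Consensus paternity** — per-patch candidate sets, an
   error-tolerant Mendelian likelihood with the per-locus mixture
   `L = (1 − e)·T(g_o | g_m, g_f) + e·P_HWE(g_o)`, unsampled fathers
   integrated over study-wide allele frequencies, self-incompatibility
   as a hard constraint, a simulated-annealing configuration search run
   five times, and acceptance of an offspring–donor pair only when it
   appears in ≥ 2 of 5 runs.
3. **Pollen-flow measures** — per receptor the within-patch
   pollination proportion `PF_within`, the pollen immigration rate
   `1 − PF_within`, and allelic richness `A_r` of the offspring rarefied
   to five individuals by the exact hypergeometric formula
   `A_r(l) = Σ_i [1 − C(N_l − N_li, g)/C(N_l, g)]` (g = 10 gene copies);
   per-donor statistics (offspring sired, distances, distance to the
   forest edge).
4. **Landscape metrics** — in 50/250/1000 m buffers: percent cover of
   maize, semi-natural grassland and rapeseed (exact disc–polygon
   intersection), lengths of roads, water courses and woody linear
   elements, their orthogonal-to-parallel (O:P) length ratios relative
   to the receptor–midpoint axis, and counts of neighbouring
   populations.
5. **Inference** — Box-Cox transformation and standardisation,
   single-metric screening at p ≤ 0.15 (separately for the conditional
   and zero-inflation components), |r| > 0.7 collinearity exclusions,
   all-subsets model selection at ΔAICc ≤ 2 with conditional averaging
   and unconditional SEs, over zero-inflated Poisson / binomial mixed
   models (adaptive 2-D Gauss–Hermite quadrature, patch random
   intercepts in both components) and Gaussian mixed models.
6. **Synthetic studies** — a trapline-mating generator (routes of 10–30
   visits, geometric pollen carryover, self-incompatibility, genotyping
   error, clonal population structure, landscape layers) with complete
   ground truth, so the whole pipeline is verifiable offline.

Everything is data-frame-first: functions take tibbles, return tibbles,
fitted objects have `tidy()` / `glance()` methods and `autoplot()`
views, and the stages compose with the pipe.

## Worked example

Simulate a mid-sized study (nine forest patches, 20–50 shoot clusters
each), run QC and paternity, and summarise pollen flow:

```r
library(pollenscape)
library(dplyr)

cfg   <- sim_config(n_clusters_range = c(20L, 50L),
                    receptors_per_patch = c(4L, 6L))
study <- simulate_study(cfg, seed = 42)

qc  <- deduplicate_genotypes(study$genotypes)
repeated_mlg_counts(study$genotypes)
#>   n_groups n_samples_involved n_redundant
#> 1       65                193         128

clonality_report(study$genotypes, study$clusters)
#> Clonality report: 59 clusters with >= 2 sampled shoots (191 single-shoot clusters excluded)
#>   overall monoclonal fraction: 0.288

pat <- assign_paternity(qc$genotypes, paternity_config(seed = 42))
glance(pat)
#>   n_offspring n_assigned prop_assigned n_incompatible n_patches
#> 1         428        197         0.460              1         9

rs <- receptor_summaries(pat, qc$genotypes)
head(select(rs, receptor_id, n_offspring, n_within, pf_within,
            immigration_rate, a_r), 2)
#>   receptor_id  n_offspring n_within pf_within immigration_rate   a_r
#> 1 F01_C0003_S1           7        3     0.429            0.571  4.68
#> 2 F01_C0009_S1          22       13     0.591            0.409  4.38

median(rs$pf_within[!rs$excluded])   #> 0.449
median(rs$a_r, na.rm = TRUE)         #> 4.67
```

Read: 46% of the 428 genotyped offspring were assigned to a pollen
donor of their own forest patch; the median
receptor received about 55% of its pollen from outside its patch
(immigration rate `1 − 0.449`), and the rarefied allelic richness of the
incoming pollen averaged ~4.7 alleles per locus. The generator's ground
truth for this run has a median within-patch proportion of 0.571 — the
estimate sits below it because within-patch fathers hiding in
multi-genet clusters are unsampled, exactly the conservative bias the
consensus rule is designed to accept. One offspring was excluded as
incompatible with its recorded mother.

The landscape and modelling stages chain the same way (see the methods
vignette in `vignettes/pollenscape-methods.Rmd`):

```r
out <- run_stage("all", run_config(out_dir = "run1", seed = 42))
# run1/ now holds allele_table.csv ... landscape_metrics.csv,
# model_report.csv, selection_table.csv and a manifest.json
```

A thin command-line wrapper is installed at
`inst/cli/pollenscape.R`:

```sh
Rscript inst/cli/pollenscape.R all --config run.yaml --seed 42 --out run1
```

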