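# aidsig

Tools for asking whether activation-induced cytidine deaminase (AID) has left a
mutagenic footprint in somatic SNV catalogs from B-cell precursor acute
lymphoblastic leukemia (BCP-ALL) — or any cancer cohort with called SNVs, a
reference FASTA, and a reference signature set. AID acts locally, so the search
has three prongs, each implemented here as tidyverse-style functions over SNV
tibbles:

1. **Mutational signature refitting.** Each sample's SNVs are classified into
   the canonical 96 trinucleotide-context channels (pyrimidine-strand
   convention) and the catalog *y* is decomposed against a fixed signature
   matrix *S* (e.g. COSMIC SBS1–30 + SBS84/85) by non-negative least squares,
   `min ||y − Sw||₂ s.t. w ≥ 0`. Relative contributions are `w / Σw`; refit
   quality is the cosine similarity between *y* and *Sw*; the AID-associated
   aggregate sums SBS9 + SBS84 + SBS85.
2. **Clustered mutations / kataegis.** Clusters are maximal chains of mutations
   with consecutive gaps ≤ 1000 bp. Signatures are refit on the clustered
   subset, gated on cosine > 0.75; candidate kataegis regions are summarised by
   C>T content and RC>NY motif fraction, and scanned for WRC>NY hotspots.
3. **AID-motif gene screen.** Per gene, the split of non-synonymous mutations
   inside/outside the RC>NY motif is tested against the gene's motif site
   content with Fisher's exact test, Benjamini–Hochberg-adjusted across genes.

Because the WGS cohorts this search was designed for are access-controlled, the
package includes a first-class synthetic-data generator (`sim_config()`,
`simulate_cohort()`, `inject_kataegis()`, `simulate_gene_mutations()`) that
produces multi-sample cohorts from known signature mixtures with injected
kataegis and motif-biased genes, plus a JSON truth manifest — every stage is
testable against exact ground truth.

## Worked example

```r
library(aidsig)

# a 4-sample synthetic cohort: 1000 mutations/sample from a mixture carrying
# an AID-like signature at weight 0.3, plus one injected kataegis cluster
cfg <- sim_config(seed = 11, n_samples = 4L, reference_length = 5000000L,
                  mutations_per_sample = 1000L)
sim <- simulate_cohort(cfg)

cat96 <- build_catalog(sim$snvs, sim$genome)
fit   <- refit(cat96, sim$signatures)
glance(fit)
#> # A tibble: 4 × 3
#>   sample_id n_mutations cosine
#>   <chr>           <int>  <dbl>
#> 1 S01              1040  0.985
#> 2 S02              1000  0.987
#> 3 S03              1000  0.981
#> 4 S04              1000  0.986

aid_contribution(fit, members = "SBS84")
#> # A tibble: 4 × 2
#>   sample_id aid_contribution
#>   <chr>                <dbl>
#> 1 S01                  0.301
#> 2 S02                  0.319
#> 3 S03                  0.368
#> 4 S04                  0.279
```

Every sample reconstructs well (cosine ≥ 0.98) and the fitted SBS84
contribution recovers the true simulated weight 0.3. The injected kataegis
event dominates the cluster report — 40 C>T mutations, 40% in the RC>NY AID
motif, exactly as configured:

```r
clusters <- find_clusters(sim$snvs, max_distance = 1000)
summarize_region(clusters, sim$snvs, sim$genome) |>
  dplyr::arrange(dplyr::desc(n)) |> head(3)
#>   sample_id     n span_bp n_c_to_t rcny_fraction
#> 1 S01          40    1720       40         0.4
#> 2 S03           7    3303        3         0.286
#> 3 S03           5    1027        0         0
```

The gene screen picks out the one panel gene simulated with motif odds ratio 8
(14 of its 20 mutations in-motif against a ~21% site fraction):

```r
run_gene_screen(sim$gene_snvs, sim$genes) |> head(2)
#>   gene    n_mut n_in_motif motif_site_count non_motif_site_count ...
#> 1 GENE001    20         14              308                 1192
#> 2 GENE033    10          7              319                 1181
```

Cohort composition tables use half-up one-decimal percentages, e.g.
`cohort_percentages(c("ETV6-RUNX1" = 49, Hyperdiploid = 53), total = 243)`
prints 20.2% and 21.8%.

`run_pipeline()` chains all stages over input files (or in-memory objects) and
writes TSV outputs plus a JSON run manifest; `plot_rainfall()`,
`plot_catalog()` and `autoplot()` on a refit give the standard ggplot2 views.
See the vignette (`vignettes/aid-footprints.Rmd`) for the model, parameter and
design discussion.

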