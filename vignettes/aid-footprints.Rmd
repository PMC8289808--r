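---
title: "Searching somatic SNV catalogs for AID mutagenesis footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching somatic SNV catalogs for AID mutagenesis footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidsig)
```

## The question

Activation-induced cytidine deaminase (AID) deaminates cytidine in single-stranded
DNA. On target it diversifies immunoglobulin genes; off target it mutates
proto-oncogenes and is implicated in several mature B-cell malignancies. Whether
AID leaves a detectable footprint in B-cell *precursor* leukemia (BCP-ALL) genomes
is less clear: AID acts locally, so its traces are expected in clustered
hypermutation (kataegis) and in target-motif-biased mutations of individual genes
rather than in genome-wide mutation load.

`aidsig` implements the three computational strategies used to look for such
footprints in whole-genome somatic SNV catalogs:

1. **Signature refitting** — express each sample's 96-channel mutation catalog as
   a non-negative combination of fixed reference signatures and quantify the
   aggregate contribution of the AID-associated signatures (SBS9, SBS84, SBS85).
2. **Clustered-mutation analysis** — detect mutation clusters by inter-mutation
   distance, refit signatures on the clustered subset with a cosine-similarity
   quality gate, and summarise candidate kataegis regions.
3. **Motif enrichment** — test, per gene, whether non-synonymous mutations fall
   in the AID target motif (RC>NY and relatives) more often than the gene's
   motif content predicts.

Patient WGS of this kind is access-controlled, so the package ships a
synthetic-data generator with exact ground truth; every stage is validated
against simulations rather than against protected data.

## The 96-channel catalog

Each somatic SNV is classified by its substitution and trinucleotide context on
the **pyrimidine strand**: a record whose reference allele is a purine is
reverse-complemented (both flanks included) before classification, so the six
substitution classes are C>A, C>G, C>T, T>A, T>C, T>G, each with 16 contexts —
the canonical 96-channel order of public SBS releases, which lets COSMIC-layout
signature files load without permutation.

Two conventions here were genuinely open and are package decisions:

* Mutations whose context contains N or that sit on a sequence end are
  **excluded and counted** (`n_excluded`), never silently dropped and never given
  an invented context. For every sample, `sum(counts) + n_excluded` equals the
  number of input records.
* Multi-allelic VCF rows are expanded into one record per SNV allele; non-SNV
  alleles (indels, MNVs) are skipped with a tally. This matches common
  signature-tool practice.
* A reference-allele mismatch against the supplied FASTA is a hard error by
  default (`skip_ref_mismatch = TRUE` downgrades it to a counted exclusion):
  coordinate or build mix-ups should surface early, not as noise.

## Refitting model

For catalog $y \in \mathbb{Z}_{\ge 0}^{96}$ and signature matrix
$S \in [0,1]^{96 \times K}$ (columns sum to 1), the fit solves

$$\hat w = \arg\min_{w \ge 0} \lVert y - S w \rVert_2$$

by non-negative least squares (Lawson–Hanson, via `pracma::lsqnonneg`). Relative
contributions are $\hat w / \sum_k \hat w_k$, and refit quality is the cosine
similarity between $y$ and its reconstruction $S\hat w$. Raw counts are fitted
rather than frequency-normalised profiles: NNLS on counts weights channels by
the evidence they carry, and relative contributions are scale-free afterwards
anyway. No sparsity pruning or bootstrapping is applied — the refit is reported
as is, and quality control happens downstream through the cosine gate.

The NNLS solution is checked in the test suite against an independent simplex
grid search (0.01 steps over the contribution simplex, optimal scale in closed
form per direction), and parameter recovery is verified end-to-end: mutations
drawn from a known mixture, placed on a simulated reference, read back through
classification and refit.

## Clustered mutations and kataegis

Clustered mutations are defined by inter-mutation distance: two mutations within
1000 bp (inclusive) are clustered. When more than two mutations co-locate the
package chains them: a cluster is a maximal run in which every *consecutive*
pair is within the distance. Chaining (rather than all-pairs) matches
rainfall-plot practice, where kataegis appears as an unbroken run of small
distances; the two-mutation definition seeds the chain. Clusters never span
chromosomes or samples, and each mutation belongs to at most one cluster.

Signatures are then refit on each sample's clustered-mutation catalog. Because
small catalogs produce unstable fits, samples are gated on reconstruction
cosine **strictly greater than 0.75**; failing samples are reported but excluded
from downstream summaries. A sample with no clustered mutations gets an empty,
failing row rather than an error.

`summarize_region()` reports, per cluster, the member count, the number of
pyrimidine-strand C>T mutations (a G>A record counts as C>T) and the fraction of
members in the RC>NY motif; `hotspot_scan()` counts WRC>NY, RC>NY and WRC>N
matches and flags clusters with two or more of each.

## AID target motifs

The motif classes are anchored on a mutated C read on the pyrimidine strand:

| class  | 5'−2 | 5'−1 | ref | alt rule |
|--------|------|------|-----|----------|
| RC>NY  | –    | R (A/G) | C | alt = T |
| WRC>NY | W (A/T) | R | C | alt = T |
| WRC>N  | W    | R    | C | any alt |

The product notation "RC>NY" is ambiguous about whether N loosens the context or
the alternate allele. The package reads it as: pyrimidine-strand C in the stated
5' context, mutated to the only pyrimidine reachable from C, namely T (so the
complementary-strand event is G>A in a C/T 3' context). This is a documented
interpretive choice and the alternate-allele constraint is configurable
(`alt_constraint = "any"`) so both readings can be compared. Both strands are
always evaluated via reverse complement, and the test suite checks the
involution property on enumerated 4-mers: a mutation and its complementary-
strand description always classify identically.

### Per-gene enrichment

For each gene with at least `min_mutations` (default 3) non-synonymous
mutations, the observed split of mutations inside/outside the motif is compared
with the gene's motif site content by Fisher's exact test on

$$\begin{pmatrix} n_\text{in} & n_\text{out} \\ m & \bar m \end{pmatrix}$$

where $m$ is the number of positions that are the mutated-C of the motif on
either strand (overlapping occurrences each counted) and $\bar m$ the remaining
positions. The denominator is the whole gene length — the literal reading of
"motif frequency in the gene sequence" — with a `denominator = "cg"` switch
restricting it to C:G positions for sensitivity analysis. P-values are adjusted
across all tested genes by Benjamini–Hochberg (`alpha` default 0.05), and rows
are ordered by the number of in-motif mutations, the "genes with most mutations
in the AID motif" presentation. Sidedness defaults to two-sided since the
original analyses do not state a direction; `sided = "greater"` is available
because the scientific hypothesis is enrichment.

## The synthetic cohort generator

The generator emulates exactly what the pipeline consumes, with known truth:

* **Reference**: i.i.d. bases at a stated GC fraction (default 0.41, the
  human genome-wide value). This is deliberately structureless — no chromatin,
  replication timing, or transcription covariates of real AID targeting — so
  passing tests demonstrate algorithmic correctness, not biological realism.
* **Background mutations**: channels drawn from the 96-dimensional mixture
  $S w$, placed uniformly among genome positions carrying the required
  pyrimidine-strand context, without site collisions. Sites whose forward
  strand carries the purine complement are emitted as complementary records
  (G>A for a C>T event), which exercises strand normalisation on roughly half
  the records.
* **Kataegis**: `inject_kataegis()` places *n* C>T mutations in a window, an
  exact `round(motif_bias * n)` of them at RC>NY sites and the rest at
  non-motif C sites, resampling until all gaps are ≤ 1000 bp so the cluster is
  recovered whole. The default spec (40 mutations, 2 kb span, bias 0.4)
  mirrors the shape of a reported CDKN2B-locus kataegis event.
* **Gene panel**: each mutation lands in-motif with probability $p^*$ where
  $p^*/(1-p^*) = \theta \cdot m/\bar m$, $\theta$ the odds ratio; $\theta = 1$
  is the null in which the in-motif fraction matches the gene's site fraction.

All randomness flows from one master seed with per-stage derived substreams
(`(seed + k·1000003) mod (2^31 - 1)`), so identical configurations yield
byte-identical output files while stages remain independently reproducible.

### Scale choices

The default cohort (`sim_config()`) uses 20 samples on a 20 Mb mini-genome with
1000 mutations each. The real study analysed 243 protected whole genomes; 20
samples keep the full pipeline demonstrable in seconds. The 20 Mb / 1000-mutation
density is denser per base than real WGS (a faithful joint scale-down of genome
size and mutation count would leave too few mutations to refit), so background
clusters are somewhat more frequent here than in patient data; the injected
kataegis still stands out by an order of magnitude. Refit-recovery experiments
use 5000 mutations per sample on a 500 kb reference — placement density is
irrelevant when no clustering is involved — and the motif screen uses 50 genes
of 1500 bp, one carrying odds ratio 8 at 20 mutations against 49 null genes at
10 mutations each. At those screen conditions the detection probability after
BH sits close to the 90% design point, so small seed batches show visible
seed-to-seed variation in empirical power; the null flag rate is comfortably
below the 5% level.

## Numerical notes

* Cosine similarity on an all-zero vector is an error (undefined), but a refit
  whose reconstruction is identically zero reports quality 0 with a warning —
  the distinction matters for orthogonal-support catalogs.
* NNLS weights are clipped at zero against solver round-off before
  normalisation; contributions therefore always sum to exactly 1 for
  non-degenerate fits.
* Signature columns are validated to sum to 1 within 1e-3 (public releases
  carry rounded probabilities) and renormalised exactly.
* Percentages in cohort tables round half *up* at one decimal
  (`round_half_up()`), matching clinical-table presentation; base R's
  `round()` rounds half to even and reproduces different digits.
* Cluster distance comparison is inclusive (`<= 1000`), reading "within
  1000 bp" inclusively; the threshold is a parameter everywhere it appears.

## Limitations

* Consequence annotation, variant calling and ortholog mapping are inputs, not
  computations: the screen trusts the `consequence` column and the supplied
  gene sequences.
* The uniform-composition reference makes motif site fractions of ~0.2 typical;
  real genes vary widely in GC and motif content, which the per-gene Fisher
  denominator handles but the generator does not emulate.
* Immunoglobulin loci — where AID activity is expected but alignment is
  unreliable — are out of scope entirely; supply pre-filtered catalogs.
* Clustered-refit conclusions depend on the 0.75 cosine gate inherited from the
  original analysis; samples with few clustered mutations fail it by design and
  say nothing about AID either way.
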