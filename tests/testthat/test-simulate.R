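test_that("simulated references are deterministic with controlled GC", {
  g1 <- simulate_reference(100000, 0.5, seed = 13)
  g2 <- simulate_reference(100000, 0.5, seed = 13)
  expect_equal(as.character(g1), as.character(g2))
  g3 <- simulate_reference(100000, 0.5, seed = 14)
  expect_false(identical(as.character(g1), as.character(g3)))
  freq <- Biostrings::letterFrequency(g1, "GC", as.prob = TRUE)
  expect_lt(abs(freq - 0.5), 0.02)
  expect_error(simulate_reference(100000, 0, seed = 1), "gc_fraction")
  expect_error(simulate_reference(100, 0.5, seed = 1), ">= 1000")
})

test_that("single-channel signatures round-trip through placement and classification", {
  genome <- simulate_reference(30000, 0.5, seed = 23)
  # one channel: A[C>A]A
  sigs <- disjoint_signatures(list(1), names = "ONE")
  snvs <- sample_signature_mutations(genome, c(ONE = 1), sigs, 50, seed = 3)
  cls <- classify_substitutions(snvs, genome)
  expect_equal(unique(cls$channel), "A[C>A]A")
  expect_equal(nrow(snvs), 50)
  # both strand representations occur in a random genome
  expect_setequal(unique(snvs$ref), c("C", "G"))
})

test_that("mixture draws reproduce the mixture profile (round trip)", {
  genome <- simulate_reference(500000, 0.41, seed = 29)
  sigs <- synthetic_signatures(c("A", "B"), seed = 12)
  w <- c(A = 0.6, B = 0.4)
  snvs <- sample_signature_mutations(genome, w, sigs, 5000, seed = 7)
  expect_equal(anyDuplicated(snvs[c("chrom", "pos")]), 0L)
  cat96 <- build_catalog(snvs, genome)
  p <- as.vector(unclass(sigs) %*% w)
  expect_gte(cosine_similarity(as_catalog_matrix(cat96)[, 1], p), 0.95)
  fit <- refit(cat96, sigs)
  expect_lt(max(abs(fit$contributions[, 1] - w)), 0.05)
  # different seeds move the sites but not the expected profile
  snvs2 <- sample_signature_mutations(genome, w, sigs, 5000, seed = 8)
  overlap <- nrow(dplyr::inner_join(snvs[c("chrom", "pos")],
                                    snvs2[c("chrom", "pos")],
                                    by = c("chrom", "pos")))
  expect_lt(overlap / 5000, 0.2)
})

test_that("weight validation rejects malformed mixtures", {
  genome <- simulate_reference(10000, 0.5, seed = 1)
  sigs <- synthetic_signatures(c("A", "B"), seed = 1)
  expect_error(sample_signature_mutations(genome, c(A = 0.5, B = 0.4), sigs, 10),
               "sum to 1")
  expect_error(sample_signature_mutations(genome, c(A = 0.5, X = 0.5), sigs, 10),
               "unknown signature")
})

test_that("unplaceable channels raise an informative error", {
  # all-AT-flavoured genome cannot host most contexts
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("AT", 2000), collapse = "")))
  sigs <- disjoint_signatures(list(1), names = "ONE")  # needs ACA context
  expect_error(sample_signature_mutations(genome, c(ONE = 1), sigs, 5, seed = 1),
               "cannot place")
})

test_that("kataegis injection hits the requested motif fraction exactly", {
  genome <- simulate_reference(200000, 0.41, seed = 31)
  kat <- inject_kataegis(genome, "chr1", 100000, 101999, n = 40,
                         motif_bias = 0.4, seed = 11)
  cl <- find_clusters(kat, 1000)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n, 40L)
  sr <- summarize_region(cl, kat, genome)
  expect_equal(sr$n_c_to_t, 40L)
  expect_equal(sr$rcny_fraction, 0.4)
  # zero bias places no motif mutations
  kat0 <- inject_kataegis(genome, "chr1", 100000, 101999, n = 20,
                          motif_bias = 0, seed = 12)
  sr0 <- summarize_region(find_clusters(kat0, 1000), kat0, genome)
  expect_equal(sr0$rcny_fraction, 0)
  # tiny windows cannot host the cluster
  expect_error(inject_kataegis(genome, "chr1", 100, 140, n = 40,
                               motif_bias = 0.4, seed = 1), "too few C sites")
})

test_that("gene mutation simulation honours the odds-ratio model", {
  gene <- Biostrings::DNAStringSet(c(
    G = as.character(simulate_reference(2000, 0.41, seed = 61)[[1]])))
  prof <- gene_motif_profile(gene, "RC>NY")
  # null odds ratio: pooled in-motif fraction tracks the site fraction
  hits <- vapply(1:8, function(s) {
    m <- simulate_gene_mutations(gene, n = 250, odds_ratio = 1, seed = s)
    sum(matches_motif(m, gene, "RC>NY"))
  }, numeric(1))
  frac <- sum(hits) / (8 * 250)
  site_frac <- prof$motif_site_count /
    (prof$motif_site_count + (prof$length_bp - prof$motif_site_count))
  expect_lt(abs(frac - site_frac), 0.03)
  expect_error(simulate_gene_mutations(gene, 10, odds_ratio = 0), "odds_ratio")
})

test_that("cohort emission round-trips and the manifest indexes every mutation", {
  cfg <- sim_config(seed = 5, reference_length = 100000L, n_samples = 3L,
                    mutations_per_sample = 60L,
                    kataegis_specs = tibble::tibble(sample = 1L, n = 12L,
                                                    span = 1500L,
                                                    motif_bias = 0.5),
                    gene_specs = tibble::tibble(length = 1200L,
                                                n_mutations = c(8L, 5L),
                                                motif_odds_ratio = c(4, 1)))
  sim <- simulate_cohort(cfg)
  outdir <- withr::local_tempdir()
  paths <- write_cohort(sim, outdir)
  # conservation: files round-trip with the configured totals
  snvs <- read_snvs(paths[["snvs"]])
  expect_equal(nrow(snvs), 3 * 60 + 12)
  expect_equal(nrow(read_snvs(paths[["gene_snvs"]])), 8 + 5)
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$n_snvs, nrow(snvs))
  expect_equal(sum(vapply(manifest$samples, `[[`, numeric(1), "n_mutations")),
               nrow(snvs))
  # manifest cluster members are recovered by find_clusters in one cluster
  # (background mutations falling within 1 kb may legitimately chain on)
  cl <- find_clusters(snvs, 1000)
  big <- cl[cl$n >= 12, ]
  expect_equal(nrow(big), 1)
  truth_pos <- unlist(manifest$clusters[[1]]$positions)
  expect_true(all(truth_pos %in% big$positions[[1]]))
  expect_equal(big$sample_id, manifest$clusters[[1]]$sample_id)
  # per-gene truth matches a fresh motif classification of the emitted records
  genes <- read_reference(paths[["genes"]])
  gsnv <- read_snvs(paths[["gene_snvs"]])
  got <- sum(matches_motif(gsnv, genes, "RC>NY"))
  expect_equal(got, sum(vapply(manifest$genes, `[[`, numeric(1), "n_in_motif")))

  # identical config => byte-identical outputs
  outdir2 <- withr::local_tempdir()
  paths2 <- write_cohort(simulate_cohort(cfg), outdir2)
  for (nm in names(paths)) {
    expect_equal(unname(tools::md5sum(paths[[nm]])),
                 unname(tools::md5sum(paths2[[nm]])), label = nm)
  }
})
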