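test_that("RC>NY evaluation follows the pyrimidine-strand reading", {
  #                                      123456
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAGCTA"))
  # C at 4 preceded by G (purine): RC context; C>T satisfies the NY rule
  hit <- snv_tbl(chrom = "chr1", pos = 4, ref = "C", alt = "T")
  expect_true(matches_motif(hit, genome, "RC>NY"))
  # C>G fails the alternate constraint but WRC>N ignores it (A at -2 is W)
  cg <- snv_tbl(chrom = "chr1", pos = 4, ref = "C", alt = "G")
  expect_false(matches_motif(cg, genome, "RC>NY"))
  expect_true(matches_motif(cg, genome, "WRC>N"))
  # relaxing the alternate constraint makes C>G an RC match too
  expect_true(matches_motif(cg, genome, "RC>NY", alt_constraint = "any"))
  # pyrimidine-strand ref T never matches a C-anchored motif
  t_rec <- snv_tbl(chrom = "chr1", pos = 5, ref = "T", alt = "C")
  expect_false(matches_motif(t_rec, genome, "RC>NY"))
})

test_that("strand involution: complementary record descriptions agree", {
  withr::local_seed(31)
  bases <- c("A", "C", "G", "T")
  # enumerate all 4-mers W R C N as chr W R C N; mutate the C (pos 3)
  grid <- expand.grid(b1 = bases, b2 = bases, b4 = bases,
                      stringsAsFactors = FALSE)
  fwd_seq <- paste0(grid$b1, grid$b2, "C", grid$b4)
  rev_seq <- aidsig:::revcomp_chr(fwd_seq)
  for (motif in c("RC>NY", "WRC>NY", "WRC>N")) {
    for (alt in c("T", "G", "A")) {
      gf <- Biostrings::DNAStringSet(stats::setNames(fwd_seq, paste0("f", seq_along(fwd_seq))))
      gr <- Biostrings::DNAStringSet(stats::setNames(rev_seq, paste0("r", seq_along(rev_seq))))
      fwd_rec <- snv_tbl(chrom = paste0("f", seq_along(fwd_seq)), pos = 3,
                         ref = "C", alt = alt)
      rev_rec <- snv_tbl(chrom = paste0("r", seq_along(rev_seq)), pos = 2,
                         ref = "G", alt = aidsig:::complement_base(alt))
      expect_equal(as.logical(matches_motif(fwd_rec, gf, motif)),
                   as.logical(matches_motif(rev_rec, gr, motif)))
    }
  }
})

test_that("insufficient flank is unevaluable, reported FALSE", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "CATG"))
  rec <- snv_tbl(chrom = "chr1", pos = 1, ref = "C", alt = "T")
  res <- matches_motif(rec, genome, "RC>NY")
  expect_false(as.logical(res))
  expect_true(attr(res, "unevaluable"))
})

test_that("gene motif profiles match a brute-force scan on both strands", {
  # worked example: every C in ACACAC is preceded by A; no G on the forward strand
  prof <- gene_motif_profile(c(g1 = "ACACAC"), "RC>NY")
  expect_equal(prof$motif_site_count, 3L)
  expect_equal(prof$motif_site_fraction, 0.5)
  expect_equal(gene_motif_profile(c(g = paste(rep("T", 50), collapse = "")),
                                  "RC>NY")$motif_site_count, 0L)
  withr::local_seed(17)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    for (motif in c("RC>NY", "WRC>N")) {
      got <- gene_motif_profile(stats::setNames(s, "g"), motif)$motif_site_count
      expect_equal(got, length(motif_sites_oracle(s, motif)))
      # strand symmetry
      rc <- aidsig:::revcomp_chr(s)
      expect_equal(gene_motif_profile(stats::setNames(rc, "g"), motif)$motif_site_count,
                   got)
    }
  }
})

test_that("Fisher enrichment p-values match the hypergeometric oracle", {
  cases <- list(c(8, 2, 20, 80), c(0, 5, 10, 50), c(5, 5, 50, 50),
                c(12, 1, 30, 300), c(3, 9, 40, 60))
  for (tb in cases) {
    expect_equal(enrichment_test(tb[1], tb[2], tb[3], tb[4], sided = "two"),
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4], "two"),
                 tolerance = 1e-10)
    expect_equal(enrichment_test(tb[1], tb[2], tb[3], tb[4], sided = "greater"),
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4], "greater"),
                 tolerance = 1e-10)
  }
  # zero observed in-motif mutations cannot support enrichment
  expect_equal(enrichment_test(0, 7, 5, 100, sided = "greater"), 1)
  # the balanced table is the mode: two-sided p = 1
  expect_equal(enrichment_test(5, 5, 50, 50, sided = "two"), 1)
  # zero mutations -> p = 1 by convention
  expect_equal(enrichment_test(0, 0, 5, 100), 1)
  expect_error(enrichment_test(1, 1, 0, 0), "positive")
})

test_that("BH adjustment: worked example, edge cases, permutation equivariance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(8)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("gene screen finds a strongly enriched gene and sorts by in-motif count", {
  genes <- Biostrings::DNAStringSet(c(
    HOT = as.character(simulate_reference(1500, 0.41, seed = 41)[[1]]),
    COLD = as.character(simulate_reference(1500, 0.41, seed = 42)[[1]])))
  hot <- simulate_gene_mutations(genes["HOT"], n = 20, odds_ratio = 12, seed = 1)
  cold <- simulate_gene_mutations(genes["COLD"], n = 10, odds_ratio = 1, seed = 2)
  screen <- run_gene_screen(dplyr::bind_rows(hot, cold), genes)
  expect_equal(screen$gene[1], "HOT")
  expect_true(screen$significant[screen$gene == "HOT"])
  expect_true(all(diff(screen$n_in_motif) <= 0))
  expect_true(all(screen$q_value >= screen$p_value))
})

test_that("screen filters by consequence, min_mutations and missing sequences", {
  genes <- Biostrings::DNAStringSet(c(
    G1 = as.character(simulate_reference(1200, 0.41, seed = 51)[[1]])))
  muts <- simulate_gene_mutations(genes["G1"], n = 6, odds_ratio = 1, seed = 3)
  syn <- dplyr::mutate(muts[1:2, ], consequence = "synonymous")
  other_gene <- dplyr::mutate(muts[3, ], gene = "MISSING", chrom = "MISSING")
  input <- dplyr::bind_rows(muts, syn, other_gene)
  expect_warning(screen <- run_gene_screen(input, genes, min_mutations = 3),
                 "without sequence")
  expect_equal(screen$gene, "G1")
  expect_equal(screen$n_mut, 6L)   # synonymous + missing-gene rows dropped
  # raising the floor excludes the gene entirely
  expect_equal(nrow(suppressWarnings(
    run_gene_screen(input, genes, min_mutations = 10))), 0)
})

test_that("cohort comparison is symmetric and matches the oracle", {
  expect_gt(compare_cohorts(50, 100, 500, 1000), 0.9)
  expect_equal(compare_cohorts(10, 10, 0, 10),
               fisher_oracle(10, 0, 0, 10, "two"), tolerance = 1e-10)
  expect_equal(compare_cohorts(7, 20, 3, 30),
               compare_cohorts(3, 30, 7, 20), tolerance = 1e-12)
  expect_error(compare_cohorts(5, 3, 1, 10), "n_in")
})
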