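test_that("rainfall distances are per-chromosome position differences", {
  snvs <- snv_tbl(chrom = "chr1", pos = c(100, 900, 5000),
                  ref = c("C", "C", "T"), alt = c("T", "G", "A"))
  rf <- rainfall(snvs)
  expect_equal(rf$distance_to_prev, c(NA, 800, 4100))
  expect_equal(rf$substitution_class, c("C>T", "C>G", "T>A"))

  multi <- snv_tbl(chrom = c("chr1", "chr2", "chr3"), pos = c(10, 20, 30),
                   ref = "C", alt = "T")
  expect_true(all(is.na(rainfall(multi)$distance_to_prev)))

  dup <- snv_tbl(chrom = "chr1", pos = c(50, 50), ref = c("C", "C"),
                 alt = c("T", "G"))
  expect_error(rainfall(dup), "duplicate")
})

test_that("purine records get pyrimidine-strand substitution classes", {
  snvs <- snv_tbl(chrom = "chr1", pos = c(10, 20), ref = c("G", "A"),
                  alt = c("A", "C"))
  expect_equal(rainfall(snvs)$substitution_class, c("C>T", "T>G"))
})

test_that("clusters are maximal chains with inclusive distance", {
  a <- snv_tbl(chrom = "chr1", pos = c(100, 900, 5000), ref = "C", alt = "T")
  cl <- find_clusters(a, 1000)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$positions[[1]], c(100, 900))
  expect_equal(cl$span_bp, 800)

  # consecutive gaps of exactly 1000 chain all three together
  b <- snv_tbl(chrom = "chr1", pos = c(100, 1100, 2100), ref = "C", alt = "T")
  cl2 <- find_clusters(b, 1000)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$n, 3L)
})

test_that("clusters never span chromosomes or samples and partition members", {
  snvs <- dplyr::bind_rows(
    snv_tbl(chrom = "chr1", pos = c(10, 500), ref = "C", alt = "T", sample_id = "s1"),
    snv_tbl(chrom = "chr2", pos = c(600, 900), ref = "C", alt = "T", sample_id = "s1"),
    snv_tbl(chrom = "chr1", pos = c(520, 940), ref = "C", alt = "T", sample_id = "s2"))
  cl <- find_clusters(snvs, 1000)
  expect_equal(nrow(cl), 3)
  expect_equal(anyDuplicated(tidyr::unnest_longer(cl, positions)[
    c("sample_id", "chrom", "positions")]), 0L)
})

test_that("find_clusters equals brute-force transitive closure on random inputs", {
  withr::local_seed(123)
  for (i in 1:25) {
    n <- sample(2:120, 1)
    pos <- sort(sample.int(50000, n))
    snvs <- snv_tbl(chrom = "chr1", pos = pos, ref = "C", alt = "T")
    got <- find_clusters(snvs, 1000)$positions
    want <- brute_force_clusters(pos, 1000)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("clustered catalog covers exactly the cluster members", {
  genome <- simulate_reference(200000, 0.5, seed = 9)
  # 10 clustered mutations in a 2 kb window + dispersed mutations >1 kb apart
  kat <- inject_kataegis(genome, "chr1", 100000, 101999, n = 10,
                         motif_bias = 0.5, seed = 2)
  disp_pos <- seq(1000L, by = 1700L, length.out = 50L)
  refb <- seq_context(genome, rep("chr1", 50), disp_pos, 0, 0)
  alt <- vapply(refb, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  disp <- snv_tbl(chrom = "chr1", pos = disp_pos, ref = refb, alt = unname(alt))
  all_snvs <- dplyr::arrange(dplyr::bind_rows(kat, disp), pos)
  cl <- find_clusters(all_snvs, 1000)
  expect_equal(sum(cl$n), 10L)
  ccat <- clustered_catalog(cl, all_snvs, genome)
  expect_equal(sum(ccat$count), 10L)
  # no clusters -> zero catalog
  empty <- clustered_catalog(cl[0, ], all_snvs, genome)
  expect_equal(sum(empty$count), 0L)
  expect_setequal(unique(empty$sample_id), "S1")
})

test_that("cosine QC gate passes exact refits and fails orthogonal ones", {
  sigs <- disjoint_signatures(list(1:10, 11:20), names = c("A", "B"))
  good <- 100 * unclass(sigs)[, "A"]
  bad <- rep(0, 96); bad[60:70] <- 10
  y <- cbind(good = good, bad = bad, empty = rep(0, 96))
  rows <- refit_clustered(y, sigs, qc_cosine = 0.75)
  expect_equal(rows$passes_qc, c(TRUE, FALSE, FALSE))
  expect_equal(rows$cosine[1], 1, tolerance = 1e-12)
  expect_equal(rows$cosine[2], 0)
  expect_true(is.na(rows$cosine[3]))
  expect_equal(rows$n_clustered, c(100L, 110L, 0L))
  expect_error(refit_clustered(y, sigs, qc_cosine = 1.2), "qc_cosine")
})

test_that("samples with many clustered mutations pass QC more often than sparse ones", {
  withr::local_seed(77)
  sigs <- synthetic_signatures(c("A", "B", "C"), seed = 5)
  p <- as.vector(unclass(sigs) %*% c(0.5, 0.3, 0.2))
  draw_catalog <- function(n) as.vector(stats::rmultinom(1, n, p))
  y <- cbind(
    sapply(1:10, function(i) draw_catalog(60)),     # rich clustered sets
    sapply(1:10, function(i) draw_catalog(3)))      # sparse ones
  colnames(y) <- sprintf("s%02d", 1:20)
  rownames(y) <- sbs_channels()
  rows <- refit_clustered(y, sigs, qc_cosine = 0.75)
  rate_rich <- mean(rows$passes_qc[1:10])
  rate_sparse <- mean(rows$passes_qc[11:20])
  expect_gt(rate_rich, rate_sparse)
})

test_that("region summaries count pyrimidine-strand C>T and RC>NY fractions", {
  #        123456789
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACTACGTT"))
  # two C>T both in RC context? pos3 C preceded by A (R) -> RC; pos6 C preceded
  # by A (pos5) -> RC. alt T on pyrimidine strand.
  snvs <- snv_tbl(chrom = "chr1", pos = c(3, 6), ref = c("C", "C"), alt = "T")
  cl <- find_clusters(snvs, 1000)
  sr <- summarize_region(cl, snvs, genome)
  expect_equal(sr$n_c_to_t, 2L)
  expect_equal(sr$rcny_fraction, 1)
  # cluster with no C:G reference members
  snvs2 <- snv_tbl(chrom = "chr1", pos = c(4, 9), ref = "T", alt = "A")
  sr2 <- summarize_region(find_clusters(snvs2, 1000), snvs2, genome)
  expect_equal(sr2$n_c_to_t, 0L)
  expect_equal(sr2$rcny_fraction, 0)
})

test_that("hotspot scan respects motif nesting and the multiple flag", {
  genome <- simulate_reference(50000, 0.5, seed = 21)
  kat <- inject_kataegis(genome, "chr1", 20000, 21999, n = 30,
                         motif_bias = 0.5, seed = 4)
  cl <- find_clusters(kat, 1000)
  hs <- hotspot_scan(cl, kat, genome)
  expect_true(all(hs$n_wrc_ny <= hs$n_rc_ny))
  expect_true(all(hs$n_wrc_ny <= hs$n_wrc_n))
  expect_equal(hs$multiple_rc_ny, hs$n_rc_ny >= 2)

  # exactly one WRC>NY member -> multiple flag is off
  g2 <- Biostrings::DNAStringSet(c(chr1 = "TTAGCTTTTTTTTTTATTTT"))
  one <- snv_tbl(chrom = "chr1", pos = c(5, 16), ref = c("C", "A"),
                 alt = c("T", "G"))
  hs2 <- hotspot_scan(find_clusters(one, 1000), one, g2)
  expect_equal(hs2$n_wrc_ny, 1L)
  expect_false(hs2$multiple_wrc_ny)
})
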