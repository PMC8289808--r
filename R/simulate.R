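## Synthetic cohort generator -------------------------------------------------
##
## Every pipeline stage is testable against known ground truth: a simulated
## reference, mutations drawn from a known signature mixture, injected
## kataegis clusters, and motif-biased gene mutations, all driven by one seed
## with per-stage derived substreams.

# Derived substream seed for stage k: (seed + k * 1000003) mod (2^31 - 1).
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Simulate a reference sequence
#'
#' I.i.d. bases at a stated GC content; deterministic for a fixed seed.
#'
#' @param length Sequence length (>= 1000).
#' @param gc_fraction GC content in (0, 1); the degenerate extremes are an
#'   error.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A single-sequence [Biostrings::DNAStringSet].
#' @export
simulate_reference <- function(length, gc_fraction = 0.41, seed = 1L,
                               name = "chr1") {
  if (length < 1000) stop("reference length must be >= 1000", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(
    4L, length, replace = TRUE,
    prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)))
  out <- Biostrings::DNAStringSet(intToUtf8(utf8ToInt("ACGT")[idx]))
  names(out) <- name
  out
}

#' Random synthetic signature set
#'
#' Draws sparse random 96-channel probability profiles (normalised gamma
#' deviates with small shape, so mass concentrates on a few channels and
#' different signatures are close to orthogonal). Useful as a refitting basis
#' in simulations; not a model of any real mutational process.
#'
#' @param names Signature names (one column each).
#' @param seed Integer seed.
#' @param shape Gamma shape controlling sparsity (smaller = sparser).
#' @return A `signature_set`.
#' @export
synthetic_signatures <- function(names = c("SBS1", "SBS5", "SBS84"), seed = 1L,
                                 shape = 0.15) {
  m <- withr::with_seed(seed, {
    vapply(seq_along(names), function(j) {
      x <- stats::rgamma(96L, shape = shape)
      # guard against an (astronomically unlikely) all-zero draw
      if (sum(x) == 0) x[1] <- 1
      x / sum(x)
    }, numeric(96L))
  })
  colnames(m) <- names
  rownames(m) <- sbs_channels()
  signature_set(m)
}

## Site index: every interior genome position keyed by its pyrimidine-strand
## trinucleotide context. Implemented on integer base codes (A=1 C=2 G=3 T=4,
## complement = 5 - code) so multi-megabase references index in seconds.

# Context id in 1..32: 5' base (4) x pyrimidine center (C/T) x 3' base (4).
pyr_ctx_id <- function(l, c, r) {
  (l - 1L) * 8L + (c == 4L) * 4L + r
}

# Context string like "ACA" (center C or T) -> id.
ctx_string_id <- function(ctx) {
  codes <- match(c(substr(ctx, 1, 1), substr(ctx, 2, 2), substr(ctx, 3, 3)),
                 DNA_BASES)
  pyr_ctx_id(codes[1], codes[2], codes[3])
}

# Per-chromosome list: positions (2..L-1) of each pyrimidine-strand context,
# split by context id. N-containing contexts are skipped.
build_site_index <- function(genome) {
  genome <- as_reference(genome)
  map <- integer(128L)
  map[utf8ToInt("ACGT")] <- 1:4
  lapply(stats::setNames(names(genome), names(genome)), function(cn) {
    v <- map[utf8ToInt(as.character(genome[[cn]]))]
    L <- length(v)
    if (L < 3L) return(list())
    l <- v[1:(L - 2L)]; c <- v[2:(L - 1L)]; r <- v[3:L]
    valid <- l > 0L & c > 0L & r > 0L
    pyr <- c == 2L | c == 4L
    lp <- ifelse(pyr, l, 5L - r)
    cp <- ifelse(pyr, c, 5L - c)
    rp <- ifelse(pyr, r, 5L - l)
    id <- pyr_ctx_id(lp, cp, rp)
    id[!valid] <- 0L
    pos <- seq.int(2L, L - 1L)
    split(pos[valid], id[valid])
  })
}

#' Draw mutations from a signature mixture over a genome
#'
#' Samples `n` substitution channels from the 96-dimensional mixture
#' `sigs %*% weights` and places each at a uniformly chosen genome position
#' with the required pyrimidine-strand trinucleotide context, without site
#' collisions. Sites whose forward strand carries the purine complement are
#' emitted as the complementary record (a C>T event at a forward-strand G is
#' written as G>A), which in a random genome happens for about half the
#' sites, exercising downstream strand normalisation.
#'
#' @param genome Reference sequence.
#' @param weights Named non-negative weights over signatures in `sigs`,
#'   summing to 1.
#' @param sigs A `signature_set`.
#' @param n Number of mutations.
#' @param seed Integer seed.
#' @param sample_id Sample name for the emitted records.
#' @param exclude Optional tibble `chrom`, `pos` of sites that must not be
#'   mutated.
#' @param site_index Precomputed context index from an internal scan of the
#'   same genome; recomputed when `NULL`. Passing it avoids rescanning the
#'   reference when placing many samples.
#' @return SNV tibble sorted by chromosome and position.
#' @export
sample_signature_mutations <- function(genome, weights, sigs, n, seed = 1L,
                                       sample_id = "S1", exclude = NULL,
                                       site_index = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  genome <- as_reference(genome)
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  unknown <- setdiff(names(weights), colnames(sigs))
  if (length(unknown)) {
    stop("weights name unknown signature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  p96 <- as.vector(unclass(sigs)[, names(weights), drop = FALSE] %*% weights)
  parts <- channel_parts()
  if (is.null(site_index)) site_index <- build_site_index(genome)
  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n, p96))
    ctx_of_channel <- paste0(parts$five_prime, parts$pyr_ref, parts$three_prime)
    out <- vector("list", 96L)
    for (ctx in unique(ctx_of_channel[counts > 0])) {
      ch_idx <- which(ctx_of_channel == ctx & counts > 0)
      needed <- sum(counts[ch_idx])
      id <- as.character(ctx_string_id(ctx))
      pool_pos <- lapply(site_index, function(ch) ch[[id]])
      pool <- tibble::tibble(
        chrom = rep(names(site_index), lengths(pool_pos)),
        pos = unlist(pool_pos, use.names = FALSE))
      if (!is.null(exclude) && nrow(exclude)) {
        pool <- dplyr::anti_join(pool, exclude[c("chrom", "pos")],
                                 by = c("chrom", "pos"))
      }
      if (nrow(pool) < needed) {
        stop("cannot place ", needed, " mutation(s) for channel(s) ",
             paste(parts$channel[ch_idx], collapse = ", "),
             ": only ", nrow(pool), " compatible site(s) with context ", ctx,
             call. = FALSE)
      }
      picked <- pool[sample.int(nrow(pool), needed), , drop = FALSE]
      picked$center <- seq_context(genome, picked$chrom, picked$pos, 0L, 0L)
      channel_assign <- rep(ch_idx, counts[ch_idx])
      for (k in seq_along(ch_idx)) {
        ci <- ch_idx[k]
        rows <- picked[channel_assign == ci, , drop = FALSE]
        on_pyr <- is_pyrimidine(rows$center)
        out[[ci]] <- tibble::tibble(
          sample_id = sample_id, chrom = rows$chrom, pos = rows$pos,
          ref = rows$center,
          alt = ifelse(on_pyr, parts$pyr_alt[ci],
                       complement_base(parts$pyr_alt[ci])))
      }
    }
    dplyr::bind_rows(out) |>
      dplyr::arrange(.data$chrom, .data$pos) |>
      dplyr::mutate(gene = NA_character_, consequence = NA_character_)
  })
}

#' Inject a kataegis cluster
#'
#' Places `n` C>T mutations (pyrimidine strand) inside a genomic window, a
#' fraction `motif_bias` of them at RC>NY target sites (pyrimidine-strand C
#' with a 5' purine) and the remainder at non-motif C sites (5' pyrimidine),
#' so that the realised RC>NY fraction is exactly `round(motif_bias * n) / n`.
#' Positions are resampled until every inter-mutation gap is at most
#' `max_gap`, guaranteeing recovery as a single cluster by [find_clusters()].
#'
#' @param genome Reference sequence.
#' @param chrom Sequence name of the target window.
#' @param start,end 1-based closed window bounds.
#' @param n Number of mutations (default 40).
#' @param motif_bias Fraction of mutations placed at RC>NY sites (default
#'   0.4).
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @param max_gap Largest allowed gap between consecutive mutations (default
#'   1000, the clustering distance).
#' @param exclude Optional tibble `chrom`, `pos` of forbidden sites.
#' @return SNV tibble of the injected mutations, sorted by position.
#' @export
inject_kataegis <- function(genome, chrom, start, end, n = 40L,
                            motif_bias = 0.4, seed = 1L, sample_id = "S1",
                            max_gap = 1000L, exclude = NULL) {
  genome <- as_reference(genome)
  if (motif_bias < 0 || motif_bias > 1) stop("motif_bias must be in [0, 1]", call. = FALSE)
  s <- as.character(genome[[chrom]])
  L <- nchar(s)
  start <- max(start, 2L); end <- min(end, L - 1L)
  pos <- start:end
  b <- substring(s, pos, pos)
  prev <- substring(s, pos - 1L, pos - 1L)
  nxt <- substring(s, pos + 1L, pos + 1L)
  # pyrimidine-strand C sites: forward C (5' neighbour = prev) or forward G
  # (5' neighbour = complement of next)
  five <- ifelse(b == "C", prev, ifelse(b == "G", complement_base(nxt), NA))
  is_c_site <- b %in% c("C", "G") & five %in% DNA_BASES
  motif_site <- is_c_site & five %in% c("A", "G")
  plain_site <- is_c_site & five %in% c("C", "T")
  motif_pos <- pos[motif_site]
  plain_pos <- pos[plain_site]
  if (!is.null(exclude) && nrow(exclude)) {
    banned <- exclude$pos[exclude$chrom == chrom]
    motif_pos <- setdiff(motif_pos, banned)
    plain_pos <- setdiff(plain_pos, banned)
  }
  n_motif <- round(motif_bias * n)
  n_plain <- n - n_motif
  if (length(motif_pos) < n_motif || length(plain_pos) < n_plain) {
    stop("window ", chrom, ":", start, "-", end, " has too few C sites (",
         length(motif_pos), " motif, ", length(plain_pos), " non-motif) for ",
         n, " mutations", call. = FALSE)
  }
  withr::with_seed(seed, {
    for (try in 1:200) {
      chosen <- sort(c(
        if (n_motif > 0) sample(motif_pos, n_motif) else integer(0),
        if (n_plain > 0) sample(plain_pos, n_plain) else integer(0)))
      if (length(chosen) < 2L || max(diff(chosen)) <= max_gap) break
      if (try == 200) stop("could not place a kataegis cluster with gaps <= ",
                           max_gap, " in ", chrom, ":", start, "-", end,
                           call. = FALSE)
    }
    refb <- substring(s, chosen, chosen)
    tibble::tibble(
      sample_id = sample_id, chrom = chrom, pos = chosen,
      ref = refb, alt = ifelse(refb == "C", "T", "A"),
      gene = NA_character_, consequence = NA_character_)
  })
}

#' Simulate motif-biased gene mutations
#'
#' Draws `n` non-synonymous mutations over one gene sequence such that each
#' lands on an AID motif target site with probability
#' \eqn{p^* = \theta r / (1 + \theta r)} where \eqn{\theta} is the requested
#' odds ratio and \eqn{r} the gene's motif/non-motif site odds. In-motif
#' mutations are C>T on the pyrimidine strand (so they satisfy the `>NY`
#' alternate rule); out-of-motif mutations get a random alternate allele.
#' `odds_ratio = 1` is the null: the expected in-motif fraction equals the
#' motif site fraction.
#'
#' @param gene_seq Gene sequence (single named entry of a `DNAStringSet`,
#'   named character, or FASTA).
#' @param n Number of mutations.
#' @param odds_ratio Enrichment odds ratio (> 0).
#' @param seed Integer seed.
#' @param motif Motif class defining the target sites.
#' @param sample_id Sample name.
#' @return Annotated SNV tibble (`chrom` and `gene` = gene name,
#'   `consequence` = `"non-synonymous"`, positions in gene coordinates).
#' @export
simulate_gene_mutations <- function(gene_seq, n, odds_ratio, seed = 1L,
                                    motif = "RC>NY", sample_id = "S1") {
  if (odds_ratio <= 0) stop("odds_ratio must be > 0", call. = FALSE)
  gene_seq <- as_reference(gene_seq)
  if (length(gene_seq) != 1L) stop("supply exactly one gene sequence", call. = FALSE)
  gene <- names(gene_seq)
  s <- as.character(gene_seq[[1L]])
  L <- nchar(s)
  sites <- motif_site_positions(s, motif)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  out_pos <- setdiff(which(b %in% DNA_BASES), sites$pos)
  if (nrow(sites) == 0L || length(out_pos) == 0L) {
    stop("gene ", gene, " needs both motif and non-motif sites", call. = FALSE)
  }
  r <- nrow(sites) / length(out_pos)
  p_star <- odds_ratio * r / (1 + odds_ratio * r)
  withr::with_seed(seed, {
    n_in <- stats::rbinom(1L, n, p_star)
    n_out <- n - n_in
    if (n_in > nrow(sites) || n_out > length(out_pos)) {
      stop("gene ", gene, " has too few sites for ", n, " mutations", call. = FALSE)
    }
    in_rows <- sites[sample.int(nrow(sites), n_in), , drop = FALSE]
    in_tbl <- tibble::tibble(
      pos = in_rows$pos,
      ref = b[in_rows$pos],
      alt = as.character(ifelse(b[in_rows$pos] == "C", "T", "A")))
    op <- if (n_out > 0) sample(out_pos, n_out) else integer(0)
    out_tbl <- tibble::tibble(
      pos = op, ref = b[op],
      alt = vapply(b[op], function(rb) sample(setdiff(DNA_BASES, rb), 1L),
                   character(1)))
    dplyr::bind_rows(in_tbl, out_tbl) |>
      dplyr::transmute(sample_id = sample_id, chrom = gene, pos = .data$pos,
                       ref = .data$ref, alt = .data$alt, gene = gene,
                       consequence = "non-synonymous") |>
      dplyr::arrange(.data$pos)
  })
}

#' Cohort simulation configuration
#'
#' Bundles the study conditions of a synthetic cohort: reference size and GC
#' content, sample count, per-sample mutation load drawn from a fixed
#' signature mixture, injected kataegis clusters, and a motif-biased gene
#' panel for the enrichment screen. Defaults give a desk-scale cohort: 20
#' samples of 1000 mutations each on a 20 Mb mini-genome (sparse enough that
#' most background mutations are unclustered) drawn from a 3-signature
#' mixture carrying an AID-associated signature at weight 0.3, one
#' 40-mutation kataegis cluster with RC>NY bias 0.4 in the first sample (the
#' shape of a reported CDKN2B kataegis event), and a 50-gene panel with one
#' odds-ratio-8 gene.
#'
#' @param seed Master seed; all stages derive substreams from it.
#' @param reference_length,gc_fraction Simulated reference size / GC.
#' @param n_samples,mutations_per_sample Cohort shape.
#' @param signatures A `signature_set` used both to generate and to refit.
#' @param signature_weights Named mixture weights (sum to 1) over
#'   `signatures`.
#' @param kataegis_specs Tibble `sample` (index), `n`, `span`, `motif_bias`;
#'   `NULL` for none.
#' @param gene_specs Tibble `length`, `n_mutations`, `motif_odds_ratio`, one
#'   row per panel gene; `NULL` for none.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       reference_length = 20000000L,
                       gc_fraction = 0.41,
                       n_samples = 20L,
                       mutations_per_sample = 1000L,
                       signatures = synthetic_signatures(c("SBS1", "SBS5", "SBS84"),
                                                         seed = 99L),
                       signature_weights = c(SBS1 = 0.4, SBS5 = 0.3, SBS84 = 0.3),
                       kataegis_specs = tibble::tibble(sample = 1L, n = 40L,
                                                       span = 2000L,
                                                       motif_bias = 0.4),
                       gene_specs = tibble::tibble(
                         length = 1500L,
                         n_mutations = c(20L, rep(10L, 49L)),
                         motif_odds_ratio = c(8, rep(1, 49L)))) {
  if (any(signature_weights < 0) || abs(sum(signature_weights) - 1) > 1e-9) {
    stop("signature_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_samples < 1L || mutations_per_sample < 1L) {
    stop("n_samples and mutations_per_sample must be positive", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), reference_length = as.integer(reference_length),
    gc_fraction = gc_fraction, n_samples = as.integer(n_samples),
    mutations_per_sample = as.integer(mutations_per_sample),
    signatures = signatures, signature_weights = signature_weights,
    kataegis_specs = kataegis_specs, gene_specs = gene_specs),
    class = "sim_config")
}

#' Simulate a cohort with ground truth
#'
#' Runs the full generator for a [sim_config()]: simulates the reference,
#' draws each sample's mutations from the signature mixture, injects the
#' requested kataegis clusters (at sites not already mutated, so no site
#' collisions occur), simulates the gene panel, and assembles a truth
#' manifest indexing every emitted mutation.
#'
#' @param config A `sim_config`.
#' @return A list with `genome`, `snvs` (genome-wide records), `genes`
#'   (panel sequences), `gene_snvs` (annotated panel records), `signatures`,
#'   and `truth` (per-sample weights, injected cluster coordinates and
#'   members, per-gene in/out-of-motif counts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  genome <- simulate_reference(config$reference_length, config$gc_fraction,
                               seed = stage_seed(seed, 1L))
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  site_index <- build_site_index(genome)

  snvs <- purrr::map_dfr(seq_len(config$n_samples), function(i) {
    sample_signature_mutations(genome, config$signature_weights,
                               config$signatures, config$mutations_per_sample,
                               seed = stage_seed(seed, 10L + i),
                               sample_id = sample_ids[i],
                               site_index = site_index)
  })

  clusters_truth <- NULL
  if (!is.null(config$kataegis_specs) && nrow(config$kataegis_specs)) {
    ks <- config$kataegis_specs
    chrom <- names(genome)[1]
    L <- config$reference_length
    injected <- purrr::map_dfr(seq_len(nrow(ks)), function(j) {
      sid <- sample_ids[ks$sample[j]]
      # windows spaced through the second half of the reference
      start <- floor(L / 2) + (j - 1L) * (max(ks$span) + 5000L)
      existing <- snvs[snvs$sample_id == sid, c("chrom", "pos")]
      kat <- inject_kataegis(genome, chrom, start, start + ks$span[j] - 1L,
                             n = ks$n[j], motif_bias = ks$motif_bias[j],
                             seed = stage_seed(seed, 100L + j),
                             sample_id = sid, exclude = existing)
      kat$spec <- j
      kat
    })
    clusters_truth <- injected |>
      dplyr::group_by(.data$spec, .data$sample_id, .data$chrom) |>
      dplyr::summarise(n = dplyr::n(), start = min(.data$pos),
                       end = max(.data$pos), positions = list(sort(.data$pos)),
                       .groups = "drop")
    snvs <- dplyr::bind_rows(snvs, injected[setdiff(names(injected), "spec")]) |>
      dplyr::arrange(.data$sample_id, .data$chrom, .data$pos)
  }

  genes <- NULL; gene_snvs <- NULL; gene_truth <- NULL
  if (!is.null(config$gene_specs) && nrow(config$gene_specs)) {
    gs <- config$gene_specs
    gene_names <- sprintf("GENE%03d", seq_len(nrow(gs)))
    seqs <- purrr::map_chr(seq_len(nrow(gs)), function(j) {
      as.character(simulate_reference(max(gs$length[j], 1000L),
                                      config$gc_fraction,
                                      seed = stage_seed(seed, 200L + j))[[1]])
    })
    seqs <- substr(seqs, 1L, gs$length)
    genes <- Biostrings::DNAStringSet(seqs)
    names(genes) <- gene_names
    gene_snvs <- purrr::map_dfr(seq_len(nrow(gs)), function(j) {
      simulate_gene_mutations(genes[j], n = gs$n_mutations[j],
                              odds_ratio = gs$motif_odds_ratio[j],
                              seed = stage_seed(seed, 300L + j),
                              sample_id = sample_ids[(j - 1L) %% length(sample_ids) + 1L])
    })
    in_motif <- matches_motif(gene_snvs, genes, motif = "RC>NY")
    gene_truth <- gene_snvs |>
      dplyr::mutate(in_motif = in_motif) |>
      dplyr::group_by(gene = .data$gene) |>
      dplyr::summarise(n_mut = dplyr::n(), n_in_motif = sum(.data$in_motif),
                       .groups = "drop") |>
      dplyr::left_join(tibble::tibble(gene = gene_names,
                                      true_odds_ratio = gs$motif_odds_ratio),
                       by = "gene")
  }

  list(
    genome = genome, snvs = snvs, genes = genes, gene_snvs = gene_snvs,
    signatures = config$signatures, config = config,
    truth = list(
      sample_weights = tibble::tibble(
        sample_id = sample_ids,
        weights = rep(list(config$signature_weights), length(sample_ids))),
      clusters = clusters_truth,
      genes = gene_truth))
}

#' Write a simulated cohort to disk
#'
#' Emits the generator output as plain-text files that round-trip through the
#' package readers: reference and gene FASTA, SNV tables in the TSV dialect,
#' the signature basis, a BED of injected kataegis windows, and a JSON truth
#' manifest. Re-running with the same configuration reproduces the files
#' byte for byte.
#'
#' @param sim Output of [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(outdir, "reference.fasta"),
    snvs = file.path(outdir, "snvs.tsv"),
    signatures = file.path(outdir, "signatures.tsv"),
    manifest = file.path(outdir, "truth_manifest.json"))
  Biostrings::writeXStringSet(sim$genome, paths[["reference"]])
  write_snvs(sim$snvs, paths[["snvs"]])
  write_signatures(sim$signatures, paths[["signatures"]])
  if (!is.null(sim$genes)) {
    paths[["genes"]] <- file.path(outdir, "genes.fasta")
    paths[["gene_snvs"]] <- file.path(outdir, "gene_snvs.tsv")
    Biostrings::writeXStringSet(sim$genes, paths[["genes"]])
    write_snvs(sim$gene_snvs, paths[["gene_snvs"]])
  }
  if (!is.null(sim$truth$clusters)) {
    paths[["regions"]] <- file.path(outdir, "kataegis_regions.bed")
    bed <- sim$truth$clusters |>
      dplyr::transmute(.data$chrom, start = .data$start - 1L, end = .data$end,
                       name = paste0("kataegis_", .data$sample_id))
    readr::write_tsv(bed, paths[["regions"]], col_names = FALSE, progress = FALSE)
  }
  manifest <- list(
    seed = sim$config$seed,
    n_samples = sim$config$n_samples,
    mutations_per_sample = sim$config$mutations_per_sample,
    signature_weights = as.list(sim$config$signature_weights),
    n_snvs = nrow(sim$snvs),
    samples = {
      counts <- dplyr::count(sim$snvs, .data$sample_id)
      purrr::map2(counts$sample_id, counts$n,
                  function(s, n) list(sample_id = s, n_mutations = n))
    },
    clusters = if (!is.null(sim$truth$clusters)) {
      purrr::pmap(sim$truth$clusters, function(spec, sample_id, chrom, n,
                                               start, end, positions) {
        list(sample_id = sample_id, chrom = chrom, n = n, start = start,
             end = end, positions = positions)
      })
    },
    genes = if (!is.null(sim$truth$genes)) {
      purrr::pmap(sim$truth$genes, function(gene, n_mut, n_in_motif,
                                            true_odds_ratio) {
        list(gene = gene, n_mut = n_mut, n_in_motif = n_in_motif,
             true_odds_ratio = true_odds_ratio)
      })
    })
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Write SNV records / a signature set as TSV
#'
#' `write_snvs()` writes the tab-separated dialect read by [read_snvs()]
#' (`sample chrom pos ref alt gene consequence`); `write_signatures()` writes
#' the channel-by-signature layout read by [load_signatures()].
#'
#' @param snvs SNV tibble.
#' @param sigs A `signature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snvs <- function(snvs, path) {
  out <- snvs |>
    dplyr::transmute(sample = .data$sample_id, .data$chrom, .data$pos,
                     .data$ref, .data$alt,
                     gene = if ("gene" %in% names(snvs)) .data$gene else NA_character_,
                     consequence = if ("consequence" %in% names(snvs))
                       .data$consequence else NA_character_)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_snvs
#' @export
write_signatures <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  out <- dplyr::bind_cols(tibble::tibble(Type = rownames(sigs)),
                          tibble::as_tibble(unclass(sigs)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
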