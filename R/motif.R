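## AID target motif classes --------------------------------------------------
##
## All motifs are anchored on a mutated C read on the pyrimidine strand:
##   RC>NY  — 5' purine neighbour (R = A/G), alternate allele T
##   WRC>NY — additionally an A/T (W) two bases 5', alternate allele T
##   WRC>N  — WRC context, any alternate allele
## A record whose reference allele is a purine is reverse-complemented first,
## so both strands are evaluated. The ">NY" alternate constraint is read as
## "the pyrimidine reachable from C", i.e. T; this interpretive choice is
## configurable via `alt_constraint`.

MOTIF_CLASSES <- c("RC>NY", "WRC>NY", "WRC>N")

#' Does a mutation match an AID target motif?
#'
#' Evaluates each SNV against one of the AID target motif classes on the
#' pyrimidine strand (purine-reference records are reverse-complemented
#' first). Mutations whose required flanking bases are N or outside the
#' sequence are unevaluable and return `FALSE`; their indices are attached as
#' the `unevaluable` attribute.
#'
#' @param snvs Tidy SNV tibble.
#' @param genome Reference sequence. Positions are looked up on
#'   `snvs$chrom`.
#' @param motif One of `"RC>NY"`, `"WRC>NY"`, `"WRC>N"`.
#' @param alt_constraint Override for the alternate-allele rule: `"motif"`
#'   (default; T for the `>NY` classes, anything for `>N`), `"T"`, or
#'   `"any"`.
#' @return Logical vector, one element per record, with attribute
#'   `unevaluable` (logical vector marking records with insufficient
#'   context).
#' @export
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AAGCTA"))
#' snv <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = 4L,
#'                       ref = "C", alt = "T")
#' matches_motif(snv, genome, "RC>NY")
matches_motif <- function(snvs, genome, motif = c("RC>NY", "WRC>NY", "WRC>N"),
                          alt_constraint = c("motif", "T", "any")) {
  motif <- match.arg(motif)
  alt_constraint <- match.arg(alt_constraint)
  validate_snvs(snvs)
  genome <- as_reference(genome)
  n <- nrow(snvs)
  if (n == 0L) {
    return(structure(logical(0), unevaluable = logical(0)))
  }
  need_w <- motif %in% c("WRC>NY", "WRC>N")
  need_alt_t <- switch(alt_constraint,
                       motif = motif %in% c("RC>NY", "WRC>NY"),
                       T = TRUE, any = FALSE)

  flip <- is_purine(snvs$ref)
  pyr_ref <- ifelse(flip, complement_base(snvs$ref), snvs$ref)
  pyr_alt <- ifelse(flip, complement_base(snvs$alt), snvs$alt)
  # 5' neighbours on the pyrimidine strand: upstream on + records, downstream
  # (complemented) on purine records
  m1 <- ifelse(flip,
               complement_base(seq_context(genome, snvs$chrom, snvs$pos + 1L, 0L, 0L)),
               seq_context(genome, snvs$chrom, snvs$pos - 1L, 0L, 0L))
  m2 <- if (need_w) {
    ifelse(flip,
           complement_base(seq_context(genome, snvs$chrom, snvs$pos + 2L, 0L, 0L)),
           seq_context(genome, snvs$chrom, snvs$pos - 2L, 0L, 0L))
  } else NULL

  unevaluable <- is.na(m1) | !m1 %in% DNA_BASES
  if (need_w) unevaluable <- unevaluable | is.na(m2) | !m2 %in% DNA_BASES

  hit <- pyr_ref == "C" & m1 %in% c("A", "G")
  if (need_w) hit <- hit & m2 %in% c("A", "T")
  if (need_alt_t) hit <- hit & pyr_alt == "T"
  hit[unevaluable] <- FALSE
  structure(as.logical(hit), unevaluable = unevaluable)
}

#' Motif target-site content of gene sequences
#'
#' Counts the positions in each sequence that are the mutated C of the motif
#' on either strand (forward-strand C with the required 5' context, or
#' forward-strand G whose reverse complement provides it), and the fraction
#' of such positions over the sequence. Overlapping occurrences are each
#' counted. This is the "expected" motif frequency a random mutation would
#' hit under no AID bias.
#'
#' @param genes A [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path of gene sequences keyed by gene symbol.
#' @param motif Motif class; the `>NY` / `>N` alternate constraint does not
#'   affect sites (it constrains mutations), so `"RC>NY"` counts RC sites and
#'   both `WRC` classes count WRC sites.
#' @param denominator `"length"` (default): fraction over all positions;
#'   `"cg"`: fraction over C:G positions only (sensitivity analysis).
#' @return Tibble `gene`, `length_bp`, `motif_site_count`,
#'   `motif_site_fraction`.
#' @export
gene_motif_profile <- function(genes, motif = c("RC>NY", "WRC>NY", "WRC>N"),
                               denominator = c("length", "cg")) {
  motif <- match.arg(motif)
  denominator <- match.arg(denominator)
  genes <- as_reference(genes)
  if (length(genes) == 0L) stop("no gene sequences supplied", call. = FALSE)
  purrr::map2_dfr(as.character(genes), names(genes), function(s, nm) {
    if (nchar(s) == 0L) stop("empty sequence for gene ", nm, call. = FALSE)
    sites <- motif_site_positions(s, motif)
    len <- nchar(s)
    denom <- if (denominator == "length") len else {
      b <- strsplit(s, "", fixed = TRUE)[[1]]
      sum(b %in% c("C", "G"))
    }
    tibble::tibble(gene = nm, length_bp = len,
                   motif_site_count = nrow(sites),
                   motif_site_fraction = if (denom > 0) nrow(sites) / denom else 0)
  })
}

# Positions (and strands) of motif C-sites in one sequence. Forward-strand
# sites are C with 5' context to the left; reverse-strand sites are G with the
# (complemented) context to the right.
motif_site_positions <- function(seq, motif) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(b)
  need_w <- motif %in% c("WRC>NY", "WRC>N")
  prev1 <- c(NA, b[-L])
  next1 <- c(b[-1], NA)
  fwd <- b == "C" & prev1 %in% c("A", "G")
  rev <- b == "G" & next1 %in% c("C", "T")   # complement of R on the - strand
  if (need_w) {
    prev2 <- c(NA, NA, b[seq_len(max(L - 2L, 0L))])
    next2 <- c(b[-(1:2)], NA, NA)
    fwd <- fwd & prev2 %in% c("A", "T")
    rev <- rev & next2 %in% c("A", "T")      # complement of W is W
  }
  tibble::tibble(
    pos = c(which(fwd), which(rev)),
    strand = rep(c("+", "-"), c(sum(fwd, na.rm = TRUE), sum(rev, na.rm = TRUE))))
}

#' Fisher's exact test for motif enrichment
#'
#' Tests whether mutations fall in the motif more often than expected from
#' the gene's motif site content, via Fisher's exact test on the 2x2 table
#' `[[n_in_motif, n_out_motif], [motif_sites, non_motif_sites]]` (exact
#' hypergeometric computation). Vectorised over rows.
#'
#' @param n_in_motif,n_out_motif Observed mutation counts inside / outside
#'   the motif.
#' @param motif_sites,non_motif_sites Motif / non-motif position counts of
#'   the gene sequence.
#' @param sided `"two"` (default) or `"greater"` (enrichment alternative).
#' @return Numeric vector of p-values. Rows with zero mutations return 1.
#' @export
enrichment_test <- function(n_in_motif, n_out_motif, motif_sites,
                            non_motif_sites, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  counts <- cbind(n_in_motif, n_out_motif, motif_sites, non_motif_sites)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(motif_sites + non_motif_sites == 0)) {
    stop("motif_sites + non_motif_sites must be positive", call. = FALSE)
  }
  alternative <- if (sided == "two") "two.sided" else "greater"
  vapply(seq_len(nrow(counts)), function(i) {
    if (counts[i, 1] + counts[i, 2] == 0) return(1)
    stats::fisher.test(matrix(counts[i, ], nrow = 2, byrow = TRUE),
                       alternative = alternative)$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene screen for AID motif mutation enrichment
#'
#' For every gene with at least `min_mutations` non-synonymous mutations,
#' compares the observed count of mutations in the AID motif against the
#' motif site content of the gene sequence (Fisher's exact test), adjusts
#' across genes by Benjamini-Hochberg, and sorts by the number of in-motif
#' mutations (descending) — the genes with most mutations in the AID motif.
#'
#' Positions in `snvs` are coordinates within the gene sequence, and
#' `snvs$chrom` must name the gene's sequence in `gene_seqs` (gene FASTA
#' keyed by symbol).
#'
#' @param snvs Annotated SNV tibble with `gene` and `consequence` columns;
#'   only records with consequence `"non-synonymous"` enter the screen.
#' @param gene_seqs Gene sequences (FASTA path, named character vector or
#'   `DNAStringSet`) keyed by gene symbol.
#' @param motif Motif class (default `"RC>NY"`).
#' @param min_mutations Minimum non-synonymous mutations for a gene to be
#'   tested (default 3).
#' @param alpha Significance level on the BH-adjusted q-value (default 0.05).
#' @param sided Fisher sidedness, `"two"` (default) or `"greater"`.
#' @param denominator Passed to [gene_motif_profile()].
#' @return Tibble with one row per tested gene: `gene`, `n_mut`,
#'   `n_in_motif`, `motif_site_count`, `non_motif_site_count`,
#'   `motif_site_fraction`, `p_value`, `q_value`, `significant`.
#' @export
run_gene_screen <- function(snvs, gene_seqs, motif = "RC>NY",
                            min_mutations = 3L, alpha = 0.05,
                            sided = c("two", "greater"),
                            denominator = c("length", "cg")) {
  sided <- match.arg(sided)
  denominator <- match.arg(denominator)
  gene_seqs <- as_reference(gene_seqs)
  if (!"gene" %in% names(snvs) || !"consequence" %in% names(snvs)) {
    stop("screen input needs `gene` and `consequence` columns", call. = FALSE)
  }
  ns <- snvs |>
    dplyr::filter(!is.na(.data$gene),
                  tolower(.data$consequence) %in% "non-synonymous")
  no_seq <- setdiff(unique(ns$gene), names(gene_seqs))
  if (length(no_seq)) {
    warning("gene(s) without sequence excluded from the screen: ",
            paste(no_seq, collapse = ", "), call. = FALSE)
    ns <- dplyr::filter(ns, !.data$gene %in% no_seq)
  }
  counts <- ns |> dplyr::count(.data$gene, name = "n_mut") |>
    dplyr::filter(.data$n_mut >= min_mutations)
  if (nrow(counts) == 0L) {
    return(tibble::tibble(gene = character(), n_mut = integer(),
                          n_in_motif = integer(), motif_site_count = integer(),
                          non_motif_site_count = integer(),
                          motif_site_fraction = double(), p_value = double(),
                          q_value = double(), significant = logical()))
  }
  ns <- dplyr::filter(ns, .data$gene %in% counts$gene)
  ns$in_motif <- matches_motif(ns, gene_seqs, motif = motif)
  profile <- gene_motif_profile(gene_seqs[unique(ns$gene)], motif = motif,
                                denominator = denominator)
  denom_count <- if (denominator == "length") {
    profile$length_bp
  } else {
    vapply(as.character(gene_seqs[profile$gene]), function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("C", "G"))
    }, integer(1))
  }
  profile$non_motif_site_count <- as.integer(denom_count - profile$motif_site_count)

  screened <- ns |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(n_mut = dplyr::n(), n_in_motif = sum(.data$in_motif),
                     .groups = "drop") |>
    dplyr::left_join(profile, by = "gene") |>
    dplyr::mutate(
      p_value = enrichment_test(.data$n_in_motif, .data$n_mut - .data$n_in_motif,
                                .data$motif_site_count, .data$non_motif_site_count,
                                sided = sided),
      q_value = bh_adjust(.data$p_value),
      significant = .data$q_value < alpha)
  screened |>
    dplyr::arrange(dplyr::desc(.data$n_in_motif), .data$p_value) |>
    dplyr::select("gene", "n_mut", "n_in_motif", "motif_site_count",
                  "non_motif_site_count", "motif_site_fraction",
                  "p_value", "q_value", "significant")
}

#' Compare motif mutation frequency between two cohorts
#'
#' Fisher's exact test on the 2x2 table of in-motif vs out-of-motif mutation
#' counts of two cohorts (e.g. KRAS mutations in a leukemia cohort vs a
#' public cancer database).
#'
#' @param n_in_a,n_a In-motif count and total for cohort A (`n_in_a <= n_a`).
#' @param n_in_b,n_b Same for cohort B.
#' @param sided `"two"` (default) or `"greater"`.
#' @return The Fisher p-value.
#' @export
compare_cohorts <- function(n_in_a, n_a, n_in_b, n_b, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (n_in_a > n_a || n_in_b > n_b || any(c(n_in_a, n_a, n_in_b, n_b) < 0)) {
    stop("need 0 <= n_in <= n for each cohort", call. = FALSE)
  }
  alternative <- if (sided == "two") "two.sided" else "greater"
  stats::fisher.test(matrix(c(n_in_a, n_a - n_in_a, n_in_b, n_b - n_in_b),
                            nrow = 2, byrow = TRUE),
                     alternative = alternative)$p.value
}
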