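#' Read somatic SNVs from a TSV or VCF file
#'
#' Reads a somatic single-nucleotide variant list into the tidy SNV layout
#' used throughout the package: one row per variant with columns `sample_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt` and, when present, `gene` and
#' `consequence`.
#'
#' The TSV dialect has a header `sample  chrom  pos  ref  alt [gene]
#' [consequence]` (tab-separated). For VCF input only CHROM/POS/REF/ALT and
#' the genotype sample column name are used: multi-allelic rows are expanded
#' into one record per SNV alternate allele, and alleles that are not single
#' nucleotides (indels, MNVs) are skipped and tallied in the `n_skipped`
#' attribute of the result.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @param sample_id Sample name used for VCF files without a genotype column.
#' @return A tibble of SNV records, ordered as in the file, with attribute
#'   `n_skipped` (count of non-SNV alleles dropped).
#' @export
read_snvs <- function(path, format = c("auto", "tsv", "vcf"), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("SNV file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- switch(format, tsv = read_snvs_tsv(path), vcf = read_snvs_vcf(path, sample_id))
  validate_snvs(out, path = path)
  out
}

read_snvs_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tab)[names(tab) == "sample"] <- "sample_id"
  required <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("TSV is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(tab$pos))
  bad <- which(is.na(pos) | is.na(tab$ref) | is.na(tab$alt) | is.na(tab$sample_id))
  if (length(bad)) {
    stop("malformed SNV row at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = tab$sample_id, chrom = tab$chrom, pos = pos,
    ref = toupper(tab$ref), alt = toupper(tab$alt),
    gene = if ("gene" %in% names(tab)) tab$gene else NA_character_,
    consequence = if ("consequence" %in% names(tab)) tab$consequence else NA_character_
  )
  attr(out, "n_skipped") <- 0L
  out
}

read_snvs_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    gt_samples <- colnames(vcf@gt)
    gt_samples <- setdiff(gt_samples, "FORMAT")
    sample_id <- if (length(gt_samples) >= 1L) gt_samples[[1L]] else
      sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  if (nrow(fix) == 0L) {
    out <- tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          gene = character(), consequence = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  # expand multi-allelic ALT; tally non-SNV alleles instead of failing
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  expanded <- tibble::tibble(
    sample_id = sample_id,
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = toupper(rep(fix$REF, n_alt)),
    alt = toupper(unlist(alts, use.names = FALSE))
  )
  is_snv <- nchar(expanded$ref) == 1L & nchar(expanded$alt) == 1L &
    expanded$ref %in% DNA_BASES & expanded$alt %in% DNA_BASES &
    expanded$ref != expanded$alt
  out <- expanded[is_snv, , drop = FALSE]
  out$gene <- NA_character_
  out$consequence <- NA_character_
  attr(out, "n_skipped") <- sum(!is_snv)
  out
}

# Shared structural validation for SNV tibbles.
validate_snvs <- function(snvs, path = NULL, require_distinct = FALSE) {
  where <- if (is.null(path)) "" else paste0(" in ", path)
  required <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(snvs))
  if (length(missing)) {
    stop("SNV table", where, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(snvs) == 0L) return(invisible(snvs))
  bad_base <- !(snvs$ref %in% DNA_BASES) | !(snvs$alt %in% DNA_BASES)
  if (any(bad_base)) {
    stop("non-ACGT ref/alt allele at row ", which(bad_base)[1], where, call. = FALSE)
  }
  if (any(snvs$ref == snvs$alt)) {
    stop("ref equals alt at row ", which(snvs$ref == snvs$alt)[1], where, call. = FALSE)
  }
  if (any(snvs$pos < 1L | is.na(snvs$pos))) {
    stop("invalid position at row ", which(snvs$pos < 1L | is.na(snvs$pos))[1],
         where, call. = FALSE)
  }
  if (require_distinct) {
    dup <- duplicated(snvs[c("sample_id", "chrom", "pos")])
    if (any(dup)) {
      stop("duplicate mutation site (same sample, chrom, pos) at row ",
           which(dup)[1], where, call. = FALSE)
    }
  }
  invisible(snvs)
}

#' Classify SNVs into the 96 trinucleotide-context channels
#'
#' Assigns each substitution to one of the 96 canonical channels on the
#' pyrimidine strand: when the reference allele is a purine (A/G) the
#' substitution and both flanking bases are reverse-complemented first, so the
#' represented reference base is always C or T. Mutations whose trinucleotide
#' context contains N, or that sit at a sequence end, get `channel = NA` and
#' are marked `excluded` (they are counted, not dropped silently).
#'
#' @param snvs Tibble of SNV records (see [read_snvs()]).
#' @param genome Reference sequence ([Biostrings::DNAStringSet], named
#'   character vector, or FASTA path).
#' @param skip_ref_mismatch If `FALSE` (default) a record whose `ref` allele
#'   does not match the reference sequence is a hard error; if `TRUE` such
#'   records are marked excluded with reason `"ref_mismatch"`.
#' @return The input tibble with added columns `pyr_ref`, `pyr_alt`,
#'   `five_prime`, `three_prime`, `channel`, `channel_index` (1-96),
#'   `excluded`, `exclude_reason`.
#' @export
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AACAG"))
#' snv <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = 3L,
#'                       ref = "C", alt = "A")
#' classify_substitutions(snv, genome)$channel
classify_substitutions <- function(snvs, genome, skip_ref_mismatch = FALSE) {
  validate_snvs(snvs)
  genome <- as_reference(genome)
  n <- nrow(snvs)
  channels <- sbs_channels()
  if (n == 0L) {
    return(dplyr::mutate(snvs, pyr_ref = character(0), pyr_alt = character(0),
                         five_prime = character(0), three_prime = character(0),
                         channel = character(0), channel_index = integer(0),
                         excluded = logical(0), exclude_reason = character(0)))
  }

  ctx <- seq_context(genome, snvs$chrom, snvs$pos, up = 1L, down = 1L)
  center <- substr(ctx, 2L, 2L)
  # center may be NA at sequence ends: check ref against the genome directly
  ref_obs <- seq_context(genome, snvs$chrom, snvs$pos, up = 0L, down = 0L)
  mismatch <- !is.na(ref_obs) & ref_obs != snvs$ref
  oob_site <- is.na(ref_obs)
  if (any(oob_site)) {
    stop("position outside the reference sequence at row ", which(oob_site)[1],
         call. = FALSE)
  }
  if (any(mismatch) && !skip_ref_mismatch) {
    i <- which(mismatch)[1]
    stop("ref allele mismatch at ", snvs$chrom[i], ":", snvs$pos[i],
         " (record ", snvs$ref[i], ", reference ", ref_obs[i], "); ",
         "use skip_ref_mismatch = TRUE to exclude such records", call. = FALSE)
  }

  five <- substr(ctx, 1L, 1L)
  three <- substr(ctx, 3L, 3L)
  flip <- is_purine(snvs$ref)
  pyr_ref <- ifelse(flip, complement_base(snvs$ref), snvs$ref)
  pyr_alt <- ifelse(flip, complement_base(snvs$alt), snvs$alt)
  f2 <- ifelse(flip, complement_base(three), five)
  t2 <- ifelse(flip, complement_base(five), three)

  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  no_ctx <- is.na(ctx)
  n_flank <- !no_ctx & (!f2 %in% DNA_BASES | !t2 %in% DNA_BASES)
  excluded[no_ctx] <- TRUE; reason[no_ctx] <- "context_out_of_bounds"
  excluded[n_flank] <- TRUE; reason[n_flank] <- "context_contains_N"
  excluded[mismatch] <- TRUE; reason[mismatch] <- "ref_mismatch"

  label <- paste0(f2, "[", pyr_ref, ">", pyr_alt, "]", t2)
  idx <- match(label, channels)
  idx[excluded] <- NA_integer_
  label[excluded] <- NA_character_
  f2[excluded] <- NA_character_; t2[excluded] <- NA_character_
  pyr_ref[excluded] <- NA_character_; pyr_alt[excluded] <- NA_character_

  dplyr::mutate(snvs,
    pyr_ref = pyr_ref, pyr_alt = pyr_alt,
    five_prime = f2, three_prime = t2,
    channel = label, channel_index = idx,
    excluded = excluded, exclude_reason = reason)
}

#' Build per-sample 96-channel mutation catalogs
#'
#' Classifies every SNV and tallies counts per sample over the 96 canonical
#' channels. Context-ambiguous mutations (N flank, sequence edge) are excluded
#' from the counts but reported, so that for every sample
#' `sum(count) + n_excluded` equals the number of input records.
#'
#' @inheritParams classify_substitutions
#' @param samples Optional character vector fixing the set (and order) of
#'   samples in the catalog; defaults to the samples present in `snvs`.
#'   Samples without records get an all-zero catalog.
#' @return A tibble with columns `sample_id`, `channel` (factor over the 96
#'   canonical channels) and `count`, 96 rows per sample, with attribute
#'   `exclusions`: a tibble `sample_id`, `n_snvs`, `n_excluded`.
#' @export
build_catalog <- function(snvs, genome, skip_ref_mismatch = FALSE, samples = NULL) {
  cls <- classify_substitutions(snvs, genome, skip_ref_mismatch = skip_ref_mismatch)
  if (is.null(samples)) samples <- unique(snvs$sample_id)
  channels <- sbs_channels()
  grid <- tidyr::expand_grid(
    sample_id = samples,
    channel = factor(channels, levels = channels)
  )
  counted <- cls |>
    dplyr::filter(!.data$excluded) |>
    dplyr::count(.data$sample_id, channel = factor(.data$channel, levels = channels),
                 name = "count")
  out <- grid |>
    dplyr::left_join(counted, by = c("sample_id", "channel")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  excl <- tibble::tibble(sample_id = samples) |>
    dplyr::left_join(
      cls |> dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(n_snvs = dplyr::n(), n_excluded = sum(.data$excluded)),
      by = "sample_id") |>
    dplyr::mutate(n_snvs = dplyr::coalesce(.data$n_snvs, 0L),
                  n_excluded = dplyr::coalesce(.data$n_excluded, 0L))
  attr(out, "exclusions") <- excl
  class(out) <- c("catalog96", class(out))
  out
}

#' Exclusion tallies of a catalog
#'
#' @param catalog A catalog built by [build_catalog()].
#' @return Tibble `sample_id`, `n_snvs`, `n_excluded`.
#' @export
catalog_exclusions <- function(catalog) {
  excl <- attr(catalog, "exclusions")
  if (is.null(excl)) stop("catalog carries no exclusion tally", call. = FALSE)
  excl
}

#' Catalog as a 96 x samples count matrix
#'
#' @param catalog Long catalog tibble from [build_catalog()] (columns
#'   `sample_id`, `channel`, `count`).
#' @return Numeric matrix with the 96 canonical channels as rows and samples
#'   as columns.
#' @export
as_catalog_matrix <- function(catalog) {
  channels <- sbs_channels()
  wide <- catalog |>
    dplyr::mutate(channel = as.character(.data$channel)) |>
    tidyr::pivot_wider(id_cols = "channel", names_from = "sample_id",
                       values_from = "count", values_fill = 0)
  m <- as.matrix(wide[match(channels, wide$channel), -1, drop = FALSE])
  rownames(m) <- channels
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("catalog is missing channel rows", call. = FALSE)
  m
}

#' Write / read a catalog as channel-by-sample TSV
#'
#' The on-disk layout is the one used by public signature tooling: 96 labelled
#' channel rows (`A[C>A]A`, ...) and one column per sample.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param path Output TSV path.
#' @return `write_catalog()` returns `path` invisibly; `read_catalog()`
#'   returns a long catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  m <- as_catalog_matrix(catalog)
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(channel = rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    channel = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  channels <- sbs_channels()
  if (!setequal(tab$channel, channels)) {
    stop("catalog file does not contain exactly the 96 canonical channels",
         call. = FALSE)
  }
  tab |>
    tidyr::pivot_longer(-"channel", names_to = "sample_id", values_to = "count") |>
    dplyr::mutate(channel = factor(.data$channel, levels = channels)) |>
    dplyr::arrange(.data$sample_id, .data$channel) |>
    dplyr::select("sample_id", "channel", "count")
}

#' Cosine similarity of two non-negative profiles
#'
#' The normalized dot product \eqn{u \cdot v / (\|u\| \|v\|)}: 1 for profiles
#' of identical shape, 0 for profiles with disjoint support. Scale-invariant
#' and symmetric; used here to compare an observed mutation catalog with its
#' signature reconstruction.
#'
#' @param u,v Non-negative numeric vectors of equal length, each with at least
#'   one nonzero entry.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  if (any(u < 0) || any(v < 0)) stop("vectors must be non-negative", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for an all-zero vector", call. = FALSE)
  }
  min(1, sum(u * v) / (nu * nv))
}
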