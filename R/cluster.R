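#' Rainfall data (inter-mutation distances)
#'
#' Computes, per sample and chromosome, the distance from each mutation to the
#' previous one along the chromosome — the data behind a rainfall plot, where
#' kataegis appears as a run of small distances. The first mutation on each
#' chromosome has `distance_to_prev = NA`.
#'
#' @param snvs Tidy SNV tibble (see [read_snvs()]). The same site appearing
#'   twice in one sample is an error.
#' @return Tibble `sample_id`, `chrom`, `pos`, `distance_to_prev`,
#'   `substitution_class` (one of the six pyrimidine-strand classes), sorted
#'   by sample, chromosome and position.
#' @export
rainfall <- function(snvs) {
  validate_snvs(snvs, require_distinct = TRUE)
  flip <- is_purine(snvs$ref)
  snvs |>
    dplyr::mutate(substitution_class = paste0(
      ifelse(flip, complement_base(.data$ref), .data$ref), ">",
      ifelse(flip, complement_base(.data$alt), .data$alt))) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::mutate(distance_to_prev = .data$pos - dplyr::lag(.data$pos)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "chrom", "pos", "distance_to_prev",
                  "substitution_class")
}

#' Find clustered mutations by inter-mutation distance
#'
#' Clusters are maximal runs of mutations on one chromosome of one sample in
#' which every consecutive pair lies within `max_distance` base pairs
#' (inclusive); the clustered-mutation definition — two mutations within
#' 1000 bp — seeds the chain, and chaining extends it transitively. Singleton
#' mutations are not clusters.
#'
#' @param snvs Tidy SNV tibble.
#' @param max_distance Maximum distance (bp) between consecutive cluster
#'   members; default 1000.
#' @return Tibble with one row per cluster: `sample_id`, `chrom`,
#'   `cluster_id`, `n`, `start`, `end`, `span_bp` and a list-column
#'   `positions` of sorted member positions.
#' @export
find_clusters <- function(snvs, max_distance = 1000L) {
  validate_snvs(snvs, require_distinct = TRUE)
  if (!is.numeric(max_distance) || max_distance < 1) {
    stop("max_distance must be >= 1", call. = FALSE)
  }
  snvs |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::mutate(
      gap = .data$pos - dplyr::lag(.data$pos),
      run = cumsum(is.na(.data$gap) | .data$gap > max_distance)) |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$run) |>
    dplyr::summarise(n = dplyr::n(),
                     start = min(.data$pos), end = max(.data$pos),
                     positions = list(sort(.data$pos)), .groups = "drop") |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::mutate(cluster_id = paste0(.data$sample_id, ":", .data$chrom, ":",
                                      dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(span_bp = .data$end - .data$start) |>
    dplyr::select("sample_id", "chrom", "cluster_id", "n", "start", "end",
                  "span_bp", "positions")
}

# Records belonging to any cluster (inner join on sample/chrom/member position).
cluster_members <- function(clusters, snvs) {
  if (nrow(clusters) == 0L) return(snvs[0, , drop = FALSE])
  keys <- clusters |>
    dplyr::select("sample_id", "chrom", "cluster_id", "positions") |>
    tidyr::unnest_longer("positions", values_to = "pos")
  dplyr::inner_join(snvs, keys, by = c("sample_id", "chrom", "pos"))
}

#' Catalog restricted to clustered mutations
#'
#' Builds a 96-channel catalog over exactly the union of cluster member
#' mutations. Samples present in `records` but without clusters get an
#' all-zero catalog so they still appear in downstream QC.
#'
#' @param clusters Cluster tibble from [find_clusters()] on the same records.
#' @param records The full SNV tibble the clusters were derived from.
#' @param genome Reference sequence.
#' @return A catalog tibble (see [build_catalog()]).
#' @export
clustered_catalog <- function(clusters, records, genome) {
  members <- cluster_members(clusters, records)
  build_catalog(members[setdiff(names(members), "cluster_id")], genome,
                samples = unique(records$sample_id))
}

#' Refit signatures on clustered mutations with a cosine QC gate
#'
#' Refits the reference signatures to each sample's clustered-mutation
#' catalog and flags samples whose reconstruction cosine exceeds the QC
#' threshold (strictly greater, default 0.75). Samples with no clustered
#' mutations get an empty, failing row rather than an error — few clustered
#' mutations are expected to produce unreliable refits, which is exactly what
#' the gate screens out.
#'
#' @param clustered Catalog tibble of clustered mutations
#'   ([clustered_catalog()]).
#' @param sigs A `signature_set`.
#' @param qc_cosine QC threshold in (0, 1); a sample passes iff
#'   `cosine > qc_cosine`.
#' @return Tibble with one row per sample: `n_clustered`, `cosine`,
#'   `passes_qc`, and a list-column `contributions` (tibble `signature`,
#'   `weight`, `contribution`; `NULL` for empty samples).
#' @export
refit_clustered <- function(clustered, sigs, qc_cosine = 0.75) {
  if (!is.numeric(qc_cosine) || qc_cosine <= 0 || qc_cosine >= 1) {
    stop("qc_cosine must be in (0, 1)", call. = FALSE)
  }
  y <- catalog_input_matrix(clustered)
  totals <- colSums(y)
  nonzero <- names(totals)[totals > 0]
  fit <- if (length(nonzero)) refit(y[, nonzero, drop = FALSE], sigs) else NULL
  per_sample <- tibble::tibble(sample_id = colnames(y),
                               n_clustered = as.integer(totals))
  if (!is.null(fit)) {
    fitted <- glance(fit) |>
      dplyr::left_join(
        tidy(fit) |> tidyr::nest(contributions = c("signature", "weight", "contribution")),
        by = "sample_id") |>
      dplyr::select("sample_id", "cosine", "contributions")
    per_sample <- dplyr::left_join(per_sample, fitted, by = "sample_id")
  } else {
    per_sample$cosine <- NA_real_
    per_sample$contributions <- list(NULL)
  }
  per_sample |>
    dplyr::mutate(passes_qc = !is.na(.data$cosine) & .data$cosine > qc_cosine)
}

#' Summarise kataegic regions
#'
#' For each cluster, counts members, C>T mutations (on the pyrimidine strand,
#' so a G>A record counts as C>T) and the fraction of members falling in the
#' RC>NY AID target motif.
#'
#' @param clusters Cluster tibble from [find_clusters()].
#' @param records The SNV tibble the clusters were derived from.
#' @param genome Reference sequence (for motif context lookup).
#' @return The cluster tibble with added `n_c_to_t`, `n_rcny`,
#'   `rcny_fraction`.
#' @export
summarize_region <- function(clusters, records, genome) {
  members <- cluster_members(clusters, records)
  if (nrow(members)) {
    flip <- is_purine(members$ref)
    pyr_class <- paste0(ifelse(flip, complement_base(members$ref), members$ref), ">",
                        ifelse(flip, complement_base(members$alt), members$alt))
    members$is_c_to_t <- pyr_class == "C>T"
    members$in_rcny <- matches_motif(members, genome, motif = "RC>NY")
    summary <- members |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(n_c_to_t = sum(.data$is_c_to_t),
                       n_rcny = sum(.data$in_rcny),
                       rcny_fraction = mean(.data$in_rcny), .groups = "drop")
  } else {
    summary <- tibble::tibble(cluster_id = character(), n_c_to_t = integer(),
                              n_rcny = integer(), rcny_fraction = double())
  }
  dplyr::left_join(clusters, summary, by = "cluster_id")
}

#' Scan clusters for AID hotspot motif mutations
#'
#' Counts, per cluster, the member mutations matching each AID motif class —
#' the strict WRC>NY hotspot, the relaxed RC>NY, and the context-only WRC>N —
#' and flags clusters containing multiple (>= 2) matches of each class.
#'
#' @inheritParams summarize_region
#' @return The cluster tibble with added `n_wrc_ny`, `n_rc_ny`, `n_wrc_n` and
#'   logical `multiple_wrc_ny`, `multiple_rc_ny`, `multiple_wrc_n`.
#' @export
hotspot_scan <- function(clusters, records, genome) {
  members <- cluster_members(clusters, records)
  if (nrow(members)) {
    members$wrc_ny <- matches_motif(members, genome, motif = "WRC>NY")
    members$rc_ny <- matches_motif(members, genome, motif = "RC>NY")
    members$wrc_n <- matches_motif(members, genome, motif = "WRC>N")
    summary <- members |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(n_wrc_ny = sum(.data$wrc_ny), n_rc_ny = sum(.data$rc_ny),
                       n_wrc_n = sum(.data$wrc_n), .groups = "drop")
  } else {
    summary <- tibble::tibble(cluster_id = character(), n_wrc_ny = integer(),
                              n_rc_ny = integer(), n_wrc_n = integer())
  }
  dplyr::left_join(clusters, summary, by = "cluster_id") |>
    dplyr::mutate(multiple_wrc_ny = .data$n_wrc_ny >= 2L,
                  multiple_rc_ny = .data$n_rc_ny >= 2L,
                  multiple_wrc_n = .data$n_wrc_n >= 2L)
}
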