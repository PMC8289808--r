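#' Round half away from zero
#'
#' Plain half-up rounding (0.05 -> 0.1 at one decimal), matching how clinical
#' tables print percentages; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort subgroup percentages
#'
#' Converts subgroup counts into one-decimal percentages of the grand total,
#' rounded half-up — the presentation used in clinical cohort tables.
#'
#' @param counts Named non-negative integer vector of subgroup counts.
#' @param total Grand total; defaults to `sum(counts)`.
#' @return Tibble `subgroup`, `n`, `percent`.
#' @export
#' @examples
#' cohort_percentages(c(`ETV6-RUNX1` = 49, Hyperdiploid = 53), total = 243)
cohort_percentages <- function(counts, total = sum(counts)) {
  if (length(counts) == 0L) stop("empty count map", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by subgroup", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  tibble::tibble(
    subgroup = names(counts),
    n = as.integer(counts),
    percent = unname(round_half_up(100 * counts / total, 1L)))
}

#' Per-group summary of AID signature contributions
#'
#' Attaches group labels to per-sample AID-associated contribution values and
#' summarises each group's median — the per-group quantities plotted when
#' comparing, e.g., BCR-ABL1 against other subtypes. Every sample must carry
#' a label.
#'
#' @param contributions Tibble `sample_id`, `aid_contribution`
#'   ([aid_contribution()]).
#' @param groups Named character vector or tibble (`sample_id`, `group`)
#'   labelling every sample.
#' @return Tibble `group`, `n`, `median_contribution`, plus a list-column
#'   `values` of the per-sample contributions (export-ready for plotting).
#' @export
group_contribution_summary <- function(contributions, groups) {
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble::tibble(sample_id = names(groups), group = unname(groups))
  }
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  unlabelled <- setdiff(contributions$sample_id, groups$sample_id)
  if (length(unlabelled)) {
    stop("sample(s) without a group label: ",
         paste(unlabelled, collapse = ", "), call. = FALSE)
  }
  contributions |>
    dplyr::inner_join(groups, by = "sample_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_contribution = stats::median(.data$aid_contribution),
      values = list(tibble::tibble(sample_id = sample_id,
                                   aid_contribution = aid_contribution)),
      .groups = "drop")
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: read SNVs, reference and signatures; build the
#' 96-channel catalog; refit signatures genome-wide; detect clustered
#' mutations, refit on them with the cosine QC gate, and summarise kataegic
#' regions; optionally run the per-gene motif screen. Stage outputs are
#' written as TSV to `outdir` together with a JSON manifest of the parameters
#' used; per-stage record counts are logged to stderr. A failing stage aborts
#' with the stage name and cause.
#'
#' @param snvs SNV file path or tidy SNV tibble.
#' @param reference Reference FASTA path or `DNAStringSet`.
#' @param signatures Signature TSV path or `signature_set`.
#' @param outdir Output directory.
#' @param gene_snvs,gene_fasta Optional annotated SNVs + gene sequences for
#'   the motif screen.
#' @param max_distance Clustering distance in bp (default 1000).
#' @param qc_cosine Clustered-refit QC threshold (default 0.75).
#' @param motif Motif class for the screen (default `"RC>NY"`).
#' @param min_mutations,alpha,sided Screen parameters (defaults 3, 0.05,
#'   two-sided).
#' @param aid_members Signatures aggregated as AID-associated; members absent
#'   from the loaded set are dropped with a message (e.g. when the basis is a
#'   synthetic set).
#' @return Invisibly, a list with the in-memory stage results (`catalog`,
#'   `fit`, `aid`, `clusters`, `clustered_refit`, `region_summary`, `screen`)
#'   and the written `paths`.
#' @export
run_pipeline <- function(snvs, reference, signatures, outdir,
                         gene_snvs = NULL, gene_fasta = NULL,
                         max_distance = 1000L, qc_cosine = 0.75,
                         motif = "RC>NY", min_mutations = 3L, alpha = 0.05,
                         sided = "two",
                         aid_members = c("SBS9", "SBS84", "SBS85")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  genome <- stage("reference", as_reference(reference))
  records <- stage("read_snvs", {
    if (is.character(snvs)) read_snvs(snvs) else {
      validate_snvs(snvs); snvs
    }
  })
  message("read_snvs: ", nrow(records), " record(s), ",
          length(unique(records$sample_id)), " sample(s)")
  sigs <- stage("signatures", {
    if (is.character(signatures)) load_signatures(signatures) else signatures
  })

  catalog <- stage("catalog", build_catalog(records, genome))
  write_catalog(catalog, file.path(outdir, "catalog.tsv"))
  message("catalog: ", sum(catalog$count), " classified, ",
          sum(catalog_exclusions(catalog)$n_excluded), " excluded")

  fit <- stage("refit", refit(catalog, sigs))
  refit_out <- tidy(fit) |>
    dplyr::select("sample_id", "signature", "contribution") |>
    tidyr::pivot_wider(names_from = "signature", values_from = "contribution") |>
    dplyr::left_join(glance(fit), by = "sample_id")
  readr::write_tsv(refit_out, file.path(outdir, "refit.tsv"), progress = FALSE)
  members <- intersect(aid_members, fit$signatures)
  if (length(members) < length(aid_members)) {
    message("aid_contribution: using available member(s) ",
            paste(members, collapse = ", "))
  }
  aid <- if (length(members)) aid_contribution(fit, members) else NULL
  if (!is.null(aid)) {
    readr::write_tsv(aid, file.path(outdir, "aid_contribution.tsv"),
                     progress = FALSE)
  }

  clusters <- stage("clusters", find_clusters(records, max_distance))
  message("clusters: ", nrow(clusters), " cluster(s)")
  clus_cat <- stage("clustered_catalog",
                    clustered_catalog(clusters, records, genome))
  clus_fit <- stage("refit_clustered",
                    refit_clustered(clus_cat, sigs, qc_cosine))
  readr::write_tsv(dplyr::select(clus_fit, -"contributions"),
                   file.path(outdir, "clustered_refit.tsv"), progress = FALSE)
  region_summary <- stage("summarize_region", {
    summarize_region(clusters, records, genome) |>
      hotspot_scan(records, genome) |>
      dplyr::select(-"positions")
  })
  readr::write_tsv(region_summary, file.path(outdir, "cluster_report.tsv"),
                   progress = FALSE)
  rain <- stage("rainfall", rainfall(records))
  readr::write_tsv(rain, file.path(outdir, "rainfall.tsv"), progress = FALSE)

  screen <- NULL
  if (!is.null(gene_snvs) && !is.null(gene_fasta)) {
    screen <- stage("motif_screen", {
      gsnv <- if (is.character(gene_snvs)) read_snvs(gene_snvs) else gene_snvs
      run_gene_screen(gsnv, gene_fasta, motif = motif,
                      min_mutations = min_mutations, alpha = alpha,
                      sided = sided)
    })
    readr::write_tsv(screen, file.path(outdir, "motif_screen.tsv"),
                     progress = FALSE)
    message("motif_screen: ", nrow(screen), " gene(s) tested, ",
            sum(screen$significant), " significant")
  }

  manifest <- list(
    parameters = list(max_distance = max_distance, qc_cosine = qc_cosine,
                      motif = motif, min_mutations = min_mutations,
                      alpha = alpha, sided = sided,
                      aid_members = aid_members),
    counts = list(n_snvs = nrow(records),
                  n_samples = length(unique(records$sample_id)),
                  n_clusters = nrow(clusters),
                  n_clustered_snvs = sum(clus_cat$count),
                  n_screen_genes = if (is.null(screen)) 0L else nrow(screen)))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(catalog = catalog, fit = fit, aid = aid, clusters = clusters,
                 clustered_refit = clus_fit, region_summary = region_summary,
                 rainfall = rain, screen = screen,
                 paths = list.files(outdir, full.names = TRUE)))
}
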