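#' Construct a signature set
#'
#' A signature set is the fixed refitting basis: a 96-row matrix whose columns
#' are reference mutational signatures (probability profiles over the 96
#' canonical channels, each column summing to 1).
#'
#' @param matrix Numeric matrix with 96 rows (rownames = canonical channel
#'   labels, any order) and named signature columns.
#' @param normalize If `TRUE`, columns are rescaled to sum exactly to 1;
#'   if `FALSE`, a column sum off 1 by more than `tol` is an error.
#' @param tol Tolerance on column sums.
#' @return An object of class `signature_set` (a 96 x K matrix in canonical
#'   row order).
#' @export
signature_set <- function(matrix, normalize = TRUE, tol = 1e-3) {
  channels <- sbs_channels()
  if (is.null(rownames(matrix))) {
    if (nrow(matrix) != 96L) stop("signature matrix must have 96 rows", call. = FALSE)
    rownames(matrix) <- channels
  }
  if (!setequal(rownames(matrix), channels)) {
    missing <- setdiff(channels, rownames(matrix))
    stop("signature matrix is missing channel row(s): ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  }
  m <- matrix[channels, , drop = FALSE]
  if (is.null(colnames(m)) || anyNA(colnames(m))) {
    stop("signature columns must be named", call. = FALSE)
  }
  if (!is.numeric(m) || anyNA(m)) stop("signature matrix must be numeric", call. = FALSE)
  if (any(m < 0)) stop("signature probabilities must be non-negative", call. = FALSE)
  sums <- colSums(m)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    if (!normalize || any(sums[off] <= 0)) {
      stop("signature column(s) not summing to 1: ",
           paste(colnames(m)[off], collapse = ", "), call. = FALSE)
    }
  }
  m <- sweep(m, 2, sums, "/")
  structure(m, class = c("signature_set", "matrix"))
}

#' Load reference signatures from a COSMIC-layout TSV
#'
#' Reads a tab-separated signature file in the layout of public SBS releases:
#' first column the trinucleotide channel label (`A[C>A]A` notation), the
#' remaining columns named signatures. Rows are reordered to the canonical
#' channel order if needed.
#'
#' @param path Path to the signature TSV.
#' @param subset Optional character vector of signature names to select (and
#'   order); naming an absent signature is an error.
#' @return A `signature_set` (96 x K matrix).
#' @export
load_signatures <- function(path, subset = NULL) {
  if (!file.exists(path)) stop("signature file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tab) < 2L) stop("signature file needs a label column and >= 1 signature column",
                           call. = FALSE)
  labels <- as.character(tab[[1L]])
  rest <- tab[, -1L, drop = FALSE]
  if (!all(vapply(rest, is.numeric, logical(1)))) {
    stop("non-numeric signature cell in ", path, call. = FALSE)
  }
  m <- as.matrix(rest)
  rownames(m) <- labels
  sigs <- signature_set(m)
  if (!is.null(subset)) sigs <- subset_signatures(sigs, subset)
  sigs
}

# Column selection with name checking.
subset_signatures <- function(sigs, names) {
  unknown <- setdiff(names, colnames(sigs))
  if (length(unknown)) {
    stop("unknown signature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(sigs[, names, drop = FALSE], class = c("signature_set", "matrix"))
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", ncol(x), " signature(s) over 96 channels: ",
      paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

## Refitting -----------------------------------------------------------------

# NNLS fit of one 96-vector against the signature basis.
refit_one <- function(y, m) {
  fit <- pracma::lsqnonneg(m, y)
  w <- pmax(fit$x, 0)
  rec <- as.vector(m %*% w)
  total <- sum(w)
  contrib <- if (total > 0) w / total else rep(0, length(w))
  cosine <- if (sum(rec) == 0 || sum(y) == 0) 0 else cosine_similarity(y, rec)
  list(weights = w, contributions = contrib, reconstructed = rec,
       cosine = cosine, degenerate = sum(rec) == 0)
}

#' Refit fixed reference signatures to mutation catalogs
#'
#' Expresses each sample's 96-channel catalog as a non-negative combination of
#' the reference signatures by non-negative least squares on raw counts:
#' weights minimise \eqn{\|y - S w\|_2} subject to \eqn{w \ge 0}. Relative
#' contributions are the weights normalised to sum to 1, and refit quality is
#' the cosine similarity between the observed catalog and its reconstruction
#' \eqn{S w}.
#'
#' @param catalog A catalog tibble from [build_catalog()] / [read_catalog()],
#'   a named 96-vector, or a 96 x samples matrix in canonical channel order.
#' @param sigs A `signature_set` ([load_signatures()], [signature_set()]).
#' @return An object of class `sig_refit` with [tidy()][generics::tidy]
#'   (per sample x signature weights and contributions) and
#'   [glance()][generics::glance] (per-sample `n_mutations`, `cosine`)
#'   methods.
#' @export
refit <- function(catalog, sigs) {
  stopifnot(inherits(sigs, "signature_set"))
  y <- catalog_input_matrix(catalog)
  if (any(y < 0)) stop("catalog counts must be non-negative", call. = FALSE)
  zero <- colSums(y) == 0
  if (any(zero)) {
    stop("all-zero catalog for sample(s): ",
         paste(colnames(y)[zero], collapse = ", "), call. = FALSE)
  }
  fits <- lapply(seq_len(ncol(y)), function(j) refit_one(y[, j], unclass(sigs)))
  structure(list(
    sample_ids = colnames(y),
    signatures = colnames(sigs),
    weights = matrix(vapply(fits, `[[`, numeric(ncol(sigs)), "weights"),
                     nrow = ncol(sigs), dimnames = list(colnames(sigs), colnames(y))),
    contributions = matrix(vapply(fits, `[[`, numeric(ncol(sigs)), "contributions"),
                           nrow = ncol(sigs), dimnames = list(colnames(sigs), colnames(y))),
    reconstructed = matrix(vapply(fits, `[[`, numeric(96L), "reconstructed"),
                           nrow = 96L, dimnames = list(sbs_channels(), colnames(y))),
    cosine = vapply(fits, `[[`, numeric(1), "cosine"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    n_mutations = colSums(y),
    catalog = y
  ), class = "sig_refit")
}

# Accept tidy catalog, vector, or matrix input.
catalog_input_matrix <- function(catalog) {
  if (is.matrix(catalog)) {
    if (nrow(catalog) != 96L) stop("catalog matrix must have 96 rows", call. = FALSE)
    if (is.null(colnames(catalog))) colnames(catalog) <- paste0("sample", seq_len(ncol(catalog)))
    y <- catalog
  } else if (is.numeric(catalog)) {
    if (length(catalog) != 96L) stop("catalog vector must have length 96", call. = FALSE)
    y <- matrix(catalog, ncol = 1, dimnames = list(sbs_channels(), "sample1"))
  } else if (is.data.frame(catalog)) {
    y <- as_catalog_matrix(catalog)
  } else {
    stop("unsupported catalog input", call. = FALSE)
  }
  storage.mode(y) <- "double"
  y
}

#' @export
print.sig_refit <- function(x, ...) {
  cat("<sig_refit> ", length(x$sample_ids), " sample(s) x ",
      length(x$signatures), " signature(s); cosine ",
      paste(sprintf("%.3f", utils::head(x$cosine, 5)), collapse = ", "),
      if (length(x$cosine) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature refit
#'
#' @param x A `sig_refit` object.
#' @param ... Unused.
#' @method tidy sig_refit
#' @return One row per sample and signature with absolute `weight`
#'   (mutation-count scale) and relative `contribution` (sums to 1 within
#'   each sample).
#' @export
tidy.sig_refit <- function(x, ...) {
  tidyr::expand_grid(sample_id = x$sample_ids, signature = x$signatures) |>
    dplyr::mutate(
      weight = x$weights[cbind(match(.data$signature, x$signatures),
                               match(.data$sample_id, x$sample_ids))],
      contribution = x$contributions[cbind(match(.data$signature, x$signatures),
                                           match(.data$sample_id, x$sample_ids))])
}

#' Per-sample refit summary
#'
#' @param x A `sig_refit` object.
#' @param ... Unused.
#' @method glance sig_refit
#' @return One row per sample: `n_mutations` and reconstruction `cosine`.
#' @export
glance.sig_refit <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids,
                 n_mutations = as.integer(round(x$n_mutations)),
                 cosine = x$cosine)
}

#' Refit quality (cosine similarity to the reconstruction)
#'
#' Compares each observed catalog with its signature reconstruction. If a
#' reconstruction is identically zero the quality is reported as 0 with a
#' warning.
#'
#' @param fit A `sig_refit` object.
#' @return Tibble `sample_id`, `cosine`.
#' @export
refit_quality <- function(fit) {
  stopifnot(inherits(fit, "sig_refit"))
  if (any(fit$degenerate)) {
    warning("zero reconstruction for sample(s): ",
            paste(fit$sample_ids[fit$degenerate], collapse = ", "),
            "; cosine reported as 0", call. = FALSE)
  }
  tibble::tibble(sample_id = fit$sample_ids, cosine = fit$cosine)
}

#' Aggregate AID-associated signature contribution
#'
#' Sums the relative contributions of the AID-associated signatures (by
#' default SBS9, SBS84 and SBS85) per sample. Members absent from the fitted
#' signature set are an error, not silently zero.
#'
#' @param fit A `sig_refit` object.
#' @param members Signature names to aggregate.
#' @return Tibble `sample_id`, `aid_contribution` (in `[0, 1]`).
#' @export
aid_contribution <- function(fit, members = c("SBS9", "SBS84", "SBS85")) {
  stopifnot(inherits(fit, "sig_refit"))
  unknown <- setdiff(members, fit$signatures)
  if (length(unknown)) {
    stop("unknown signature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(members, fit$signatures)
  tibble::tibble(
    sample_id = fit$sample_ids,
    aid_contribution = unname(colSums(fit$contributions[idx, , drop = FALSE])))
}
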