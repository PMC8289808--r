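# Independent oracles and small fixture builders shared across test files.
# Each oracle deliberately uses a different algorithm than the implementation
# it checks.

# Brute-force clustering: pairwise within-distance links, transitive closure
# by repeated boolean matrix products, components of size >= 2.
brute_force_clusters <- function(pos, max_distance) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_distance
  repeat {
    nxt <- ((adj %*% adj) > 0) | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  groups <- split(pos, comp)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  unname(lapply(groups, sort))
}

# Fisher's exact test from the factorial formula: hypergeometric point
# probabilities summed over at-least-as-extreme tables.
fisher_oracle <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  point <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- vapply(xs, point, numeric(1))
  p_obs <- point(a)
  if (sided == "greater") {
    sum(probs[xs >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# Loop-based motif site scan over one sequence (both strands).
motif_sites_oracle <- function(seq, motif) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(b)
  need_w <- motif %in% c("WRC>NY", "WRC>N")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- integer(0)
  for (i in seq_len(L)) {
    # forward strand: C at i with 5' context to the left
    if (identical(b[i], "C") && i >= 2 && b[i - 1] %in% c("A", "G") &&
        (!need_w || (i >= 3 && b[i - 2] %in% c("A", "T")))) {
      hits <- c(hits, i)
    }
    # reverse strand: G at i; 5' context lies to the right, complemented
    if (identical(b[i], "G") && i <= L - 1 &&
        !is.na(comp[b[i + 1]]) && comp[b[i + 1]] %in% c("A", "G") &&
        (!need_w || (i <= L - 2 && !is.na(comp[b[i + 2]]) &&
                       comp[b[i + 2]] %in% c("A", "T")))) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Simplex grid search refit oracle: directions on the contribution simplex at
# the given step, optimal non-negative scale per direction in closed form.
# Returns the minimum residual norm over the grid.
grid_refit_residual <- function(y, sigs, step = 0.01) {
  m <- unclass(sigs)
  k <- ncol(m)
  g <- round(1 / step)
  dirs <- if (k == 1) {
    matrix(1, nrow = 1)
  } else if (k == 2) {
    w1 <- seq(0, g) / g
    rbind(w1, 1 - w1)
  } else if (k == 3) {
    combos <- expand.grid(a = 0:g, b = 0:g)
    combos <- combos[combos$a + combos$b <= g, ]
    rbind(combos$a, combos$b, g - combos$a - combos$b) / g
  } else {
    stop("grid oracle supports K <= 3")
  }
  md <- m %*% dirs
  num <- as.vector(crossprod(y, md))
  den <- colSums(md^2)
  s <- pmax(0, num / pmax(den, .Machine$double.eps))
  res2 <- sum(y^2) - 2 * s * num + s^2 * den
  sqrt(max(0, min(res2)))
}

# Residual norm of a fitted sig_refit for one sample.
refit_residual <- function(fit, sample = 1L) {
  sqrt(sum((fit$catalog[, sample] - fit$reconstructed[, sample])^2))
}

# Signature set with disjoint single-channel support: useful for exact cases.
disjoint_signatures <- function(channels_per_sig, names = NULL) {
  k <- length(channels_per_sig)
  if (is.null(names)) names <- paste0("SIG", seq_len(k))
  m <- matrix(0, 96, k, dimnames = list(sbs_channels(), names))
  for (j in seq_len(k)) {
    idx <- channels_per_sig[[j]]
    m[idx, j] <- 1 / length(idx)
  }
  signature_set(m)
}

# SNV tibble shorthand.
snv_tbl <- function(chrom, pos, ref, alt, sample_id = "S1",
                    gene = NA_character_, consequence = NA_character_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, gene = gene, consequence = consequence)
}
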