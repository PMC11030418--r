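# kNN neighbor graph over spot coordinates (restricted within tissues) and
# the graph cross-product statistics used for spatial autocorrelation and
# pairwise local correlation, both calibrated by within-tissue permutation.

#' Build a within-tissue kNN neighbor graph over spots
#'
#' k nearest neighbors by Euclidean distance on the array coordinates,
#' computed independently per tissue (`sample_id` x `slide_id`), so no edge
#' ever crosses tissues -- equivalent to shifting each tissue's coordinates
#' by a large offset before a global kNN search, provided the shift exceeds
#' the tissue diameter. Each spot's neighborhood is its k neighbors plus
#' itself, all with equal weight; neighbor lists are directed (no
#' symmetrisation). Distance ties are broken by spot index order.
#'
#' @param positions numeric matrix or data frame of spot coordinates
#'   (columns `array_row`, `array_col`, or any 2+ numeric columns), rows
#'   named by barcode.
#' @param tissue_ids per-spot tissue identifier (e.g.
#'   `paste(sample_id, slide_id)`).
#' @param k number of neighbors (default 6).
#' @return A `neighbor_graph`: `nn` (spot x k neighbor index matrix,
#'   excluding self), `adj` (sparse spot x spot 0/1 matrix including self
#'   loops), `k`, `tissue` (per-spot tissue id), `barcodes`.
#' @export
build_knn_graph <- function(positions, tissue_ids, k = 6L) {
  if (is.data.frame(positions)) {
    cn <- intersect(c("array_row", "array_col"), colnames(positions))
    coords <- as.matrix(positions[, if (length(cn) == 2) cn else
      which(vapply(positions, is.numeric, logical(1)))[1:2]])
    rn <- if ("barcode" %in% colnames(positions)) positions$barcode
          else rownames(positions)
  } else {
    coords <- as.matrix(positions)
    rn <- rownames(positions)
  }
  n <- nrow(coords)
  .assert(length(tissue_ids) == n, "build_knn_graph",
          "tissue_ids must align with positions")
  tiss <- as.character(tissue_ids)
  blocks <- split(seq_len(n), tiss)
  small <- names(blocks)[vapply(blocks, length, 1L) <= k]
  if (length(small)) {
    .fail("build_knn_graph",
          sprintf("tissue(s) with <= k spots: %s",
                  paste(small, collapse = ", ")))
  }
  nn <- matrix(NA_integer_, n, k)
  for (b in blocks) {
    d <- as.matrix(stats::dist(coords[b, , drop = FALSE]))
    for (ii in seq_along(b)) {
      ord <- order(d[ii, ], seq_along(b))   # ties broken by index order
      ord <- ord[ord != ii][seq_len(k)]
      nn[b[ii], ] <- b[ord]
    }
  }
  adj <- Matrix::sparseMatrix(
    i = c(rep(seq_len(n), k), seq_len(n)),
    j = c(as.vector(nn), seq_len(n)),
    x = 1, dims = c(n, n))
  structure(list(nn = nn, adj = adj, k = as.integer(k), tissue = tiss,
                 barcodes = rn),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d spots, k = %d, %d tissue(s)\n",
              nrow(x$nn), x$k, length(unique(x$tissue))))
  invisible(x)
}

#' Depth-standardised count residuals
#'
#' Standardises counts against the depth-proportional null `c_sg ~
#' mean d_s * p_g` with a negative-binomial variance: `x_sg = (c_sg - d_s
#' p_g) / sqrt(d_s p_g (1 + d_s p_g / alpha_g))`, where `p_g` is the pooled
#' gene frequency and the per-gene dispersion `alpha_g` is estimated by
#' method of moments (the Poisson limit `alpha -> Inf` is used when the
#' observed variance does not exceed the Poisson variance).
#'
#' @param counts spot x gene count matrix.
#' @param spot_totals per-spot depths; default `rowSums(counts)`.
#' @return spot x gene numeric residual matrix.
#' @export
standardized_residuals <- function(counts, spot_totals = rowSums(counts)) {
  cnt <- .as_matrix(counts)
  d <- as.numeric(spot_totals)
  .assert(all(d > 0), "standardized_residuals", "spot totals must be > 0")
  gt <- colSums(cnt)
  if (any(gt <= 0)) {
    .fail("standardized_residuals",
          sprintf("%d gene(s) with zero total counts; exclude them upstream",
                  sum(gt <= 0)))
  }
  p_hat <- gt / sum(d)
  mu <- outer(d, p_hat)
  resid2 <- colSums((cnt - mu)^2)
  excess <- resid2 - colSums(mu)          # NB excess variance sum mu^2/alpha
  alpha_inv <- ifelse(excess > 0, excess / colSums(mu^2), 0)
  v <- mu + mu^2 * rep(alpha_inv, each = nrow(mu))
  x <- (cnt - mu) / sqrt(v)
  dimnames(x) <- dimnames(cnt)
  x
}

# within-tissue permutation of spot indices
.perm_within <- function(blocks, n) {
  p <- seq_len(n)
  for (b in blocks) p[b] <- b[sample.int(length(b))]
  p
}

#' Spatial autocorrelation of gene residuals on a neighbor graph
#'
#' Statistic `H_g = sum_i sum_{j in N(i) + self} x_ig x_jg / (k + 1)`
#' (equal weights, self included). Significance comes from a within-tissue
#' permutation null: residual rows are permuted inside each tissue,
#' preserving each gene's marginal distribution while destroying spatial
#' arrangement. Z is the permutation z-score, p the one-sided
#' (high-statistic) permutation p-value, and FDR the Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param residuals spot x gene residual matrix
#'   (see [standardized_residuals()]).
#' @param graph a [build_knn_graph()] result over the same spots.
#' @param n_perm number of permutations (warns below 100).
#' @param seed integer seed for the permutation stream.
#' @param min_tissue_spots smallest tissue size accepted (default 20; relax
#'   only for toy graphs).
#' @return An `autocorr_result` data frame: `gene`, `H`, `Z`, `p`, `fdr`.
#' @export
autocorrelation <- function(residuals, graph, n_perm = 1000L, seed = 1L,
                            min_tissue_spots = 20L) {
  X <- .as_matrix(residuals)
  .assert(nrow(X) == nrow(graph$nn), "autocorrelation",
          "residuals and graph must cover identical spot sets")
  blocks <- split(seq_len(nrow(X)), graph$tissue)
  if (any(vapply(blocks, length, 1L) < min_tissue_spots)) {
    .fail("autocorrelation",
          sprintf("tissue(s) with < %d spots", min_tissue_spots))
  }
  if (n_perm < 100) {
    warning("autocorrelation: n_perm < 100 gives coarse p-values")
  }
  A <- graph$adj
  w <- graph$k + 1
  H <- colSums(X * as.matrix(A %*% X)) / w
  G <- ncol(X)
  null_sum <- numeric(G); null_sq <- numeric(G); ge <- numeric(G)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      pidx <- .perm_within(blocks, nrow(X))
      Xp <- X[pidx, , drop = FALSE]
      Hp <- colSums(Xp * as.matrix(A %*% Xp)) / w
      null_sum <- null_sum + Hp
      null_sq <- null_sq + Hp^2
      ge <- ge + (Hp >= H)
    }
  })
  mu <- null_sum / n_perm
  sdv <- sqrt(pmax(null_sq / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  Z <- ifelse(sdv > 0, (H - mu) / sdv, 0)
  p <- (1 + ge) / (n_perm + 1)
  out <- data.frame(gene = colnames(X), H = H, Z = Z, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("autocorr_result", "data.frame")
  out
}

#' Pairwise local correlation of gene residuals on a neighbor graph
#'
#' `C_gh = sum_i sum_{j in N(i) + self} (x_ig x_jh + x_ih x_jg) /
#' (2 (k + 1))`, a symmetric graph-weighted cross-product whose diagonal
#' equals the autocorrelation statistic `H_g` exactly. The null permutes one
#' gene of each pair within tissues; `Z` is the permutation z-score and `p`
#' the one-sided (high) permutation p-value, both symmetrised.
#'
#' @param residuals spot x gene residual matrix.
#' @param graph a [build_knn_graph()] result.
#' @param gene_set character or integer subset of at least 2 genes.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A `local_corr` object: `C`, `Z`, `p` (symmetric gene x gene
#'   matrices), `genes`, `n_perm`.
#' @export
local_correlation <- function(residuals, graph, gene_set, n_perm = 1000L,
                              seed = 1L) {
  X <- .as_matrix(residuals)
  if (is.character(gene_set)) {
    missing <- setdiff(gene_set, colnames(X))
    .assert(length(missing) == 0, "local_correlation",
            sprintf("genes absent from residuals: %s",
                    paste(head(missing, 5), collapse = ", ")))
    X <- X[, gene_set, drop = FALSE]
  } else {
    X <- X[, gene_set, drop = FALSE]
  }
  .assert(ncol(X) >= 2, "local_correlation", "need >= 2 genes")
  blocks <- split(seq_len(nrow(X)), graph$tissue)
  A <- graph$adj
  B <- A + Matrix::t(A)
  w2 <- 2 * (graph$k + 1)
  M <- crossprod(X, as.matrix(A %*% X))
  C <- (M + t(M)) / w2
  G <- ncol(X)
  ns <- matrix(0, G, G); nq <- matrix(0, G, G); ge <- matrix(0, G, G)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      pidx <- .perm_within(blocks, nrow(X))
      Np <- crossprod(X, as.matrix(B %*% X[pidx, , drop = FALSE])) / w2
      ns <- ns + Np
      nq <- nq + Np^2
      ge <- ge + (Np >= C)
    }
  })
  mu <- ns / n_perm
  sdv <- sqrt(pmax(nq / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  Z <- ifelse(sdv > 0, (C - mu) / sdv, 0)
  p <- (1 + ge) / (n_perm + 1)
  # entry [g,h] of the null permutes gene h; keep the upper triangle
  # (permuting the larger-index gene of each pair) and mirror
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(C) <- dimnames(Z) <- dimnames(p) <- list(colnames(X), colnames(X))
  structure(list(C = C, Z = Z, p = p, genes = colnames(X),
                 n_perm = as.integer(n_perm)),
            class = "local_corr")
}

#' @export
print.local_corr <- function(x, ...) {
  cat(sprintf("local_corr: %d genes, %d permutations; off-diagonal |Z| max %.2f\n",
              length(x$genes), x$n_perm,
              max(abs(x$Z[upper.tri(x$Z)]))))
  invisible(x)
}
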