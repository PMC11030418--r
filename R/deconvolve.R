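# Per-spot multinomial-mixture deconvolution. Each spot's counts are
# modelled as Multinomial(d_s, p(theta)) with p_g(theta) = sum_k theta_k
# phi_kg; theta is fitted by EM (the log-likelihood is concave in theta, so
# a uniform start suffices) and reads are allocated to states by their
# posterior responsibilities, giving the cell-state-specific expected counts
# z[s,k,g] = c_sg * theta_k phi_kg / sum_k' theta_k' phi_k'g.

#' Filter spatial spots and genes before deconvolution and module detection
#'
#' Genes expressed in `min_gene_spots_exclusive` or fewer spots are removed
#' (the default removes genes seen in <= 3 spots), then spots with fewer
#' than `min_spot_genes` detected genes or fewer than `min_spot_umis` total
#' UMIs are removed. Boundary reads are strict: a spot with exactly 1000
#' genes and 1000 UMIs is retained; a gene seen in exactly 3 spots is
#' removed.
#'
#' @param spots a `spot_dataset`.
#' @param min_spot_genes,min_spot_umis spot-level thresholds.
#' @param min_gene_spots_exclusive genes expressed in this many spots or
#'   fewer are dropped.
#' @return the filtered `spot_dataset`.
#' @export
filter_spots_and_genes <- function(spots, min_spot_genes = 1000L,
                                   min_spot_umis = 1000L,
                                   min_gene_spots_exclusive = 3L) {
  cnt <- spots$counts
  keep_g <- Matrix::colSums(cnt > 0) > min_gene_spots_exclusive
  cnt <- cnt[, keep_g, drop = FALSE]
  detected <- Matrix::rowSums(cnt > 0)
  total <- Matrix::rowSums(cnt)
  keep_s <- detected >= min_spot_genes & total >= min_spot_umis
  if (!any(keep_s) || !any(keep_g)) {
    .fail("filter_spots_and_genes", "no spots/genes left after filtering")
  }
  subset_spot_dataset(spots, which(keep_s), which(keep_g))
}

subset_spot_dataset <- function(spots, spot_idx, gene_idx = NULL) {
  cnt <- spots$counts[spot_idx, , drop = FALSE]
  if (!is.null(gene_idx)) cnt <- cnt[, gene_idx, drop = FALSE]
  bc <- rownames(cnt)
  structure(list(
    counts = cnt,
    positions = spots$positions[match(bc, spots$positions$barcode), ,
                                drop = FALSE],
    samples = spots$samples[match(bc, spots$samples$barcode), ,
                            drop = FALSE]),
    class = "spot_dataset")
}

#' Deconvolve spot counts into cell-state fractions and specific counts
#'
#' Fits, independently per spot, the maximum-likelihood mixture weights
#' theta of a multinomial mixture over the reference state profiles, and
#' allocates each observed read to states by posterior responsibility. The
#' EM update is `theta_k <- sum_g c_g r_gk / sum_g c_g` with
#' `r_gk = theta_k phi_kg / sum_k' theta_k' phi_k'g`; iteration stops when
#' the relative log-likelihood improvement falls below `tol`. Profile
#' entries of exactly zero facing a positive count are floored at
#' `phi_floor` with a warning.
#'
#' @param spots a `spot_dataset`, already restricted or restrictable to the
#'   reference gene universe (genes absent from the reference are dropped).
#' @param ref a `reference_profile`.
#' @param max_iter,tol EM controls.
#' @param phi_floor numerical floor for zero profile entries.
#' @param keep_trace if `TRUE`, retain the per-spot log-likelihood trace
#'   (`loglik_trace`, list of numeric vectors) for diagnostics.
#' @return A `spot_deconv` object: `theta` (spot x state, rows sum to 1),
#'   `z` (list over states of spot x gene sparse matrices of expected
#'   state-specific counts), `loglik` (per-spot final log-likelihood),
#'   `n_iter` (per-spot iterations), `states`, `genes`, `spots` (the
#'   filtered dataset actually used).
#' @export
deconvolve <- function(spots, ref, max_iter = 1000L, tol = 1e-8,
                       phi_floor = 1e-12, keep_trace = FALSE) {
  phi <- ref$profile
  genes <- intersect(colnames(spots$counts), colnames(phi))
  .assert(length(genes) >= 2, "deconvolve",
          "need >= 2 shared genes between spots and reference")
  cnt <- .as_matrix(spots$counts[, genes, drop = FALSE])
  phi <- phi[, genes, drop = FALSE]
  K <- nrow(phi); S <- nrow(cnt)
  zero_cols <- which(apply(phi == 0, 2, any))
  if (length(zero_cols)) {
    hit <- zero_cols[colSums(cnt[, zero_cols, drop = FALSE]) > 0]
    if (length(hit)) {
      warning(sprintf(
        "deconvolve: %d gene(s) with zero reference probability in some state but positive counts; flooring phi at %g",
        length(hit), phi_floor))
    }
  }
  phi <- pmax(phi, phi_floor)
  phi <- phi / rowSums(phi)

  theta <- matrix(0, S, K, dimnames = list(rownames(cnt), rownames(phi)))
  loglik <- numeric(S)
  n_iter <- integer(S)
  resp_alloc <- vector("list", K)  # per state: spot x gene expected counts
  for (k in seq_len(K)) resp_alloc[[k]] <- matrix(0, S, length(genes))

  trace <- if (keep_trace) vector("list", S) else NULL
  tphi <- t(phi)  # gene x state
  for (s in seq_len(S)) {
    c_s <- cnt[s, ]
    nz <- which(c_s > 0)
    if (!length(nz)) {
      theta[s, ] <- 1 / K
      next
    }
    th <- rep(1 / K, K)
    ll_old <- -Inf
    it <- 0L
    tr <- numeric(0)
    phin <- tphi[nz, , drop = FALSE]
    cn <- c_s[nz]
    total <- sum(cn)
    repeat {
      it <- it + 1L
      mix <- as.vector(phin %*% th)            # p_g(theta), nz genes
      ll <- sum(cn * log(mix))
      if (keep_trace) tr <- c(tr, ll)
      r <- phin * rep(th, each = length(nz))   # theta_k phi_kg
      r <- r / mix                             # responsibilities, rows sum 1
      th_new <- colSums(cn * r) / total
      conv <- is.finite(ll_old) &&
        (ll - ll_old) <= tol * max(1, abs(ll))
      th <- th_new
      if (conv || it >= max_iter) {
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    theta[s, ] <- th
    loglik[s] <- ll_old
    n_iter[s] <- it
    if (keep_trace) trace[[s]] <- tr
    # final responsibility-weighted allocation at the converged theta
    mix <- as.vector(phin %*% th)
    r <- phin * rep(th, each = length(nz))
    r <- r / mix
    for (k in seq_len(K)) resp_alloc[[k]][s, nz] <- cn * r[, k]
  }
  z <- lapply(seq_len(K), function(k) {
    m <- Matrix::Matrix(resp_alloc[[k]], sparse = TRUE)
    dimnames(m) <- list(rownames(cnt), genes)
    m
  })
  names(z) <- rownames(phi)
  structure(list(theta = theta, z = z, loglik = loglik, n_iter = n_iter,
                 loglik_trace = trace,
                 states = rownames(phi), genes = genes,
                 spots = subset_spot_dataset(spots,
                   match(rownames(cnt), rownames(spots$counts)),
                   match(genes, colnames(spots$counts)))),
            class = "spot_deconv")
}

#' @export
print.spot_deconv <- function(x, ...) {
  cat(sprintf("spot_deconv: %d spots x %d states over %d genes\n",
              nrow(x$theta), length(x$states), length(x$genes)))
  cat(sprintf("  mean fractions: %s\n",
              paste(sprintf("%s=%.3f", x$states, colMeans(x$theta)),
                    collapse = ", ")))
  cat(sprintf("  EM iterations: median %d, max %d\n",
              as.integer(stats::median(x$n_iter)), max(x$n_iter)))
  invisible(x)
}

#' @export
summary.spot_deconv <- function(object, ...) {
  s <- list(n_spots = nrow(object$theta), n_states = length(object$states),
            n_genes = length(object$genes),
            theta_summary = apply(object$theta, 2, summary),
            total_loglik = sum(object$loglik))
  class(s) <- "summary.spot_deconv"
  s
}

#' @export
print.summary.spot_deconv <- function(x, ...) {
  cat(sprintf("Multinomial-mixture deconvolution: %d spots, %d states, %d genes\n",
              x$n_spots, x$n_states, x$n_genes))
  cat(sprintf("  total log-likelihood: %.2f\n", x$total_loglik))
  print(round(x$theta_summary, 4))
  invisible(x)
}

#' @export
coef.spot_deconv <- function(object, ...) object$theta

#' @export
fitted.spot_deconv <- function(object, ...) {
  out <- Reduce(`+`, object$z)
  .as_matrix(out)
}

#' Extract tumor-specific counts from a deconvolution
#'
#' Sums the posterior state-specific expected counts over the tumor states
#' and rounds up (ceiling), yielding an integer spot x gene matrix suitable
#' for count-based spatial statistics.
#'
#' @param result a `spot_deconv`.
#' @param tumor_states character or integer subset of `result$states`.
#' @return spot x gene integer matrix (dense).
#' @export
tumor_counts <- function(result, tumor_states) {
  if (length(tumor_states) == 0) {
    .fail("tumor_counts", "tumor_states must be non-empty")
  }
  if (is.character(tumor_states)) {
    missing <- setdiff(tumor_states, result$states)
    .assert(length(missing) == 0, "tumor_counts",
            sprintf("unknown state(s): %s", paste(missing, collapse = ", ")))
    idx <- match(tumor_states, result$states)
  } else {
    idx <- as.integer(tumor_states)
  }
  acc <- Reduce(`+`, result$z[idx])
  # guard against float noise lifting exact integers to the next ceiling
  out <- ceiling(pmax(.as_matrix(acc) - 1e-9, 0))
  storage.mode(out) <- "integer"
  out
}

#' Per-spot fraction of a group of states
#'
#' @param result a `spot_deconv`.
#' @param state_group subset of states (possibly empty).
#' @return named numeric vector of per-spot summed fractions in `[0, 1]`.
#' @export
celltype_fraction_map <- function(result, state_group) {
  if (length(state_group) == 0) {
    return(setNames(rep(0, nrow(result$theta)), rownames(result$theta)))
  }
  idx <- if (is.character(state_group)) match(state_group, result$states)
         else as.integer(state_group)
  .assert(!anyNA(idx), "celltype_fraction_map", "unknown state in group")
  rowSums(result$theta[, idx, drop = FALSE])
}

#' Replicate concordance of deconvolved fractions over annotated regions
#'
#' Averages each replicate's fractions within annotated regions and reports
#' Pearson correlations per cell type (across regions) and per region
#' (across cell types) between the two replicates.
#'
#' @param resultA,resultB `spot_deconv` objects sharing the state set.
#' @param region_labels_A,region_labels_B named per-spot region labels for
#'   each replicate (names = barcodes); regions are an input annotation,
#'   not computed.
#' @return list with `region_means_A`/`region_means_B` (region x state),
#'   `r_celltype` (per state), `r_region` (per region).
#' @export
replicate_concordance <- function(resultA, resultB,
                                  region_labels_A, region_labels_B) {
  .assert(identical(resultA$states, resultB$states),
          "replicate_concordance", "replicates must share the state set")
  mA <- .region_means(resultA, region_labels_A)
  mB <- .region_means(resultB, region_labels_B)
  regions <- intersect(rownames(mA), rownames(mB))
  if (length(regions) < 2) {
    .fail("replicate_concordance",
          "need >= 2 shared regions for cell-type-level correlation")
  }
  mA <- mA[regions, , drop = FALSE]
  mB <- mB[regions, , drop = FALSE]
  r_celltype <- vapply(seq_len(ncol(mA)),
                       function(k) cor(mA[, k], mB[, k]), numeric(1))
  names(r_celltype) <- colnames(mA)
  r_region <- vapply(seq_len(nrow(mA)),
                     function(r) cor(mA[r, ], mB[r, ]), numeric(1))
  names(r_region) <- regions
  list(region_means_A = mA, region_means_B = mB,
       r_celltype = r_celltype, r_region = r_region)
}

.region_means <- function(result, region_labels) {
  bc <- intersect(rownames(result$theta), names(region_labels))
  .assert(length(bc) > 0, "replicate_concordance",
          "region labels do not match any deconvolved spot")
  th <- result$theta[bc, , drop = FALSE]
  lab <- region_labels[bc]
  rowsum(th, lab) / as.vector(table(lab)[sort(unique(lab))])
}
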