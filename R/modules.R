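# Gene selection and bottom-up module detection on the pairwise local
# correlation Z matrix, plus smoothed per-spot module scores.

#' Select genes for module detection
#'
#' Keeps genes with spatial autocorrelation FDR strictly below `fdr_max`,
#' intersects with the transcription-factor list, and truncates to the
#' `top_n` genes by autocorrelation Z (ties broken by gene identifier).
#'
#' @param acorr an `autocorr_result` from [autocorrelation()].
#' @param tf_list character vector of transcription-factor gene names.
#' @param fdr_max FDR cutoff (strict: FDR exactly equal is excluded).
#' @param top_n maximum number of genes retained.
#' @return character vector of selected genes (warns when empty).
#' @export
select_module_genes <- function(acorr, tf_list, fdr_max = 0.01,
                                top_n = 500L) {
  sig <- acorr[acorr$fdr < fdr_max & acorr$gene %in% tf_list, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("select_module_genes: no significant transcription factors")
    return(character(0))
  }
  sig <- sig[order(-sig$Z, sig$gene), , drop = FALSE]
  sig$gene[seq_len(min(top_n, nrow(sig)))]
}

#' Detect gene modules by bottom-up merging of local-correlation Z
#'
#' Agglomerative clustering on the symmetric pairwise Z matrix: one-sided
#' pair p-values are Benjamini-Hochberg adjusted across all gene pairs; the
#' merge threshold is the smallest Z among pairs significant at
#' `fdr_threshold`; clusters are then merged iteratively by highest average
#' cross-pair Z (average linkage) while the best linkage stays at or above
#' that threshold, ties broken by smallest gene identifier. With
#' `core_only`, final clusters smaller than `min_gene_threshold` are
#' dissolved to unassigned (`-1`).
#'
#' @param localcorr a `local_corr` from [local_correlation()].
#' @param min_gene_threshold minimum module size.
#' @param fdr_threshold BH-FDR cutoff defining significant pairs.
#' @param core_only dissolve undersized clusters to unassigned.
#' @return A `module_result`: `assignment` (named integer vector, module
#'   ids `1..M`, unassigned `-1`), `modules` (list of gene sets), `z_threshold`.
#' @export
detect_modules <- function(localcorr, min_gene_threshold = 15L,
                           fdr_threshold = 0.05, core_only = TRUE) {
  Z <- localcorr$Z
  P <- localcorr$p
  genes <- localcorr$genes
  G <- length(genes)
  up <- which(upper.tri(Z))
  fdr <- p.adjust(P[up], method = "BH")
  sig <- fdr < fdr_threshold
  empty <- structure(list(
    assignment = setNames(rep(-1L, G), genes),
    modules = list(), z_threshold = NA_real_), class = "module_result")
  if (!any(sig)) return(empty)
  z_thresh <- min(Z[up][sig])

  # average-linkage agglomeration over the Z matrix
  L <- Z
  diag(L) <- -Inf
  members <- as.list(seq_len(G))
  sizes <- rep(1L, G)
  active <- rep(TRUE, G)
  lead <- genes  # smallest member gene id per cluster, for tie-breaking
  repeat {
    Lact <- L
    Lact[!active, ] <- -Inf
    Lact[, !active] <- -Inf
    Lact[lower.tri(Lact, diag = TRUE)] <- -Inf
    best <- max(Lact)
    if (!is.finite(best) || best < z_thresh) break
    cand <- which(Lact == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key <- paste(pmin(lead[cand[, 1]], lead[cand[, 2]]),
                   pmax(lead[cand[, 1]], lead[cand[, 2]]))
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    a <- cand[1, 1]; b <- cand[1, 2]
    # weighted average linkage: new cross-pair mean
    newL <- (sizes[a] * L[a, ] + sizes[b] * L[b, ]) / (sizes[a] + sizes[b])
    L[a, ] <- newL; L[, a] <- newL
    L[a, a] <- -Inf
    active[b] <- FALSE
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    lead[a] <- min(lead[a], lead[b])
    L[b, ] <- -Inf; L[, b] <- -Inf
  }
  clusters <- members[active & sizes >= if (core_only) min_gene_threshold else 2L]
  if (!length(clusters)) return(empty)
  ord <- order(-vapply(clusters, length, 1L),
               vapply(clusters, function(m) min(genes[m]), ""))
  clusters <- clusters[ord]
  assignment <- setNames(rep(-1L, G), genes)
  for (i in seq_along(clusters)) assignment[clusters[[i]]] <- i
  structure(list(
    assignment = assignment,
    modules = lapply(clusters, function(m) sort(genes[m])),
    z_threshold = z_thresh), class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  M <- length(x$modules)
  cat(sprintf("module_result: %d module(s), %d/%d genes assigned (Z threshold %.3g)\n",
              M, sum(x$assignment != -1L), length(x$assignment),
              x$z_threshold))
  for (i in seq_len(M)) {
    cat(sprintf("  module %d (%d genes): %s%s\n", i,
                length(x$modules[[i]]),
                paste(head(x$modules[[i]], 6), collapse = ", "),
                if (length(x$modules[[i]]) > 6) ", ..." else ""))
  }
  invisible(x)
}

#' Smoothed per-spot module scores
#'
#' For each module, the mean over its genes of per-gene z-scored normalised
#' expression, followed by one round of neighbor averaging over the graph
#' (self included, equal weights).
#'
#' @param norm_expr spot x gene normalised expression matrix.
#' @param modules a `module_result` (or list of gene sets).
#' @param graph a [build_knn_graph()] result over the same spots.
#' @return spot x module numeric matrix.
#' @export
module_scores <- function(norm_expr, modules, graph) {
  sets <- if (inherits(modules, "module_result")) modules$modules else modules
  sets <- sets[vapply(sets, length, 1L) > 0]
  .assert(length(sets) > 0, "module_scores", "no non-empty modules")
  X <- .as_matrix(norm_expr)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  Xz <- sweep(sweep(X, 2, mu), 2, ifelse(sdv > 0, sdv, 1), `/`)
  raw <- vapply(sets, function(g) {
    g <- intersect(g, colnames(Xz))
    rowMeans(Xz[, g, drop = FALSE])
  }, numeric(nrow(X)))
  smooth <- as.matrix(graph$adj %*% raw) / (graph$k + 1)
  dimnames(smooth) <- list(rownames(X),
                           if (is.null(names(sets)))
                             sprintf("module%d", seq_along(sets))
                           else names(sets))
  smooth
}
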