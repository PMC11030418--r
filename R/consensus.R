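# Module robustness by multinomial read subsampling: re-detect modules on
# subsampled counts and score each gene's co-occurrence with its full-data
# module partners (consensus score).

#' Multinomially subsample reads per tissue
#'
#' Per tissue, draws `floor(fraction * tissue_total)` reads from a
#' multinomial with probabilities proportional to the tissue's (spot, gene)
#' counts. Zero cells stay zero; the output total per tissue is exact.
#'
#' @param counts spot x gene count matrix.
#' @param tissue_ids per-spot tissue identifier.
#' @param fraction fraction of reads to keep, in (0, 1).
#' @param seed integer seed.
#' @return integer count matrix of the same shape.
#' @export
subsample_counts <- function(counts, tissue_ids, fraction = 0.6, seed = 1L) {
  .assert(fraction > 0 && fraction < 1, "subsample_counts",
          "fraction must be in (0,1)")
  cnt <- .as_matrix(counts)
  blocks <- split(seq_len(nrow(cnt)), as.character(tissue_ids))
  out <- matrix(0L, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  with_seed(seed, {
    for (b in blocks) {
      sub <- cnt[b, , drop = FALSE]
      total <- sum(sub)
      if (total == 0) .fail("subsample_counts", "tissue with zero reads")
      size <- floor(fraction * total)
      drawn <- rmultinom(1, size, prob = as.vector(sub))
      out[b, ] <- matrix(as.integer(drawn), nrow = length(b))
    }
  })
  out
}

#' Consensus scores from replicate module assignments
#'
#' For each gene pair co-moduled in the full-data run, the co-occurrence
#' frequency is the fraction of replicates in which both genes share a
#' module (a replicate where either gene is unassigned counts as not
#' co-occurring). A gene's consensus score is the mean frequency over its
#' full-data module partners; genes unassigned in the full-data run get no
#' score.
#'
#' @param full_modules `module_result` of the full-data run.
#' @param replicate_modules list of `module_result`s over the same genes.
#' @param threshold selection cutoff on the average consensus score
#'   (inclusive).
#' @return A `consensus_result`: `pair_cooccurrence` (data frame gene1,
#'   gene2, frequency), `gene_consensus` (named numeric), `selected_genes`,
#'   `threshold`, `n_reps`.
#' @export
consensus_scores <- function(full_modules, replicate_modules,
                             threshold = 0.8) {
  fa <- full_modules$assignment
  genes <- names(fa)
  assigned <- genes[fa != -1L]
  n_reps <- length(replicate_modules)
  .assert(n_reps >= 1, "consensus_scores", "need >= 1 replicate")
  pairs <- NULL
  for (m in unique(fa[fa != -1L])) {
    g <- sort(genes[fa == m])
    if (length(g) >= 2) {
      idx <- utils::combn(length(g), 2)
      pairs <- rbind(pairs, data.frame(gene1 = g[idx[1, ]],
                                       gene2 = g[idx[2, ]],
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs)) {
    return(structure(list(
      pair_cooccurrence = data.frame(gene1 = character(0),
                                     gene2 = character(0),
                                     frequency = numeric(0)),
      gene_consensus = setNames(numeric(0), character(0)),
      selected_genes = character(0), threshold = threshold,
      n_reps = n_reps), class = "consensus_result"))
  }
  co <- numeric(nrow(pairs))
  for (rep_m in replicate_modules) {
    ra <- rep_m$assignment[genes]
    a1 <- ra[pairs$gene1]; a2 <- ra[pairs$gene2]
    co <- co + (a1 != -1L & a2 != -1L & a1 == a2)
  }
  pairs$frequency <- co / n_reps
  gene_consensus <- vapply(assigned, function(g) {
    sel <- pairs$gene1 == g | pairs$gene2 == g
    if (!any(sel)) return(NA_real_)
    mean(pairs$frequency[sel])
  }, numeric(1))
  gene_consensus <- gene_consensus[!is.na(gene_consensus)]
  structure(list(
    pair_cooccurrence = pairs,
    gene_consensus = gene_consensus,
    selected_genes = sort(names(gene_consensus)[gene_consensus >= threshold]),
    threshold = threshold, n_reps = n_reps), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d replicate(s); %d/%d genes selected at >= %g\n",
              x$n_reps, length(x$selected_genes),
              length(x$gene_consensus), x$threshold))
  invisible(x)
}

#' Run the subsampling consensus analysis
#'
#' Repeats `n_reps` times: multinomially subsample `fraction` of the reads
#' per tissue from the (deconvolved tumor) count matrix, recompute
#' standardised residuals and pairwise local correlations over the fixed
#' full-data gene selection, re-detect modules, and score co-occurrence
#' against the full-data modules. Gene selection is not redone per
#' replicate. Per-replicate seeds derive from `master_seed + replicate`.
#'
#' @param counts spot x gene count matrix the full-data modules were
#'   computed from (typically the tumor-specific counts).
#' @param graph the [build_knn_graph()] used for the full-data run.
#' @param genes the full-data module-detection gene set.
#' @param full_modules the full-data `module_result`.
#' @param n_reps number of subsampling replicates (> 0).
#' @param fraction read fraction per replicate.
#' @param threshold selection cutoff on the average consensus score.
#' @param n_perm permutations per replicate local-correlation run.
#' @param master_seed integer master seed.
#' @param min_gene_threshold,fdr_threshold,core_only module-detection
#'   parameters (match the full-data run).
#' @return A `consensus_result` with an extra `replicate_assignments`
#'   (gene x replicate integer matrix).
#' @export
run_consensus <- function(counts, graph, genes, full_modules,
                          n_reps = 100L, fraction = 0.6, threshold = 0.8,
                          n_perm = 200L, master_seed = 1L,
                          min_gene_threshold = 15L, fdr_threshold = 0.05,
                          core_only = TRUE) {
  .assert(n_reps >= 1, "run_consensus", "n_reps must be >= 1")
  if (!length(full_modules$modules)) {
    warning("run_consensus: full-data run has zero modules")
    return(consensus_scores(full_modules,
                            replicate_modules = list(full_modules),
                            threshold = threshold))
  }
  reps <- vector("list", n_reps)
  assignments <- matrix(NA_integer_, length(genes), n_reps,
                        dimnames = list(genes, NULL))
  for (r in seq_len(n_reps)) {
    s <- derive_seed(master_seed, r)
    sub <- subsample_counts(counts, graph$tissue, fraction = fraction,
                            seed = s)
    keep <- colSums(sub) > 0
    totals <- rowSums(sub)
    .assert(all(totals > 0), "run_consensus",
            "subsampled replicate has empty spots; increase depth or fraction")
    resid <- standardized_residuals(sub[, keep, drop = FALSE], totals)
    g_here <- intersect(genes, colnames(resid))
    lc <- local_correlation(resid, graph, g_here, n_perm = n_perm,
                            seed = derive_seed(s, 7L))
    mod <- detect_modules(lc, min_gene_threshold = min_gene_threshold,
                          fdr_threshold = fdr_threshold,
                          core_only = core_only)
    asn <- setNames(rep(-1L, length(genes)), genes)
    asn[names(mod$assignment)] <- mod$assignment
    mod$assignment <- asn
    reps[[r]] <- mod
    assignments[, r] <- asn
  }
  out <- consensus_scores(full_modules, reps, threshold = threshold)
  out$replicate_assignments <- assignments
  out
}
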