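# Benchmarking the deconvolved workflow against the naive workflow on raw
# counts: paired one-sided tests on autocorrelation Z over cell-type marker
# sets and on |Z| of pairwise local correlations by marker-pair category,
# plus the bulk signature contrast used to validate modules externally.

#' Top marker genes per coarse cell type for benchmarking
#'
#' From marker-selection statistics, returns per coarse type the genes
#' passing the p/LFC thresholds, ranked by minimum log2 fold change
#' (descending, ties broken by gene identifier) and truncated to `top_n`.
#' Warns when fewer than `top_n` genes pass.
#'
#' @param marker_stats the `stats` data frame from [select_markers()] (or
#'   the whole [select_markers()] result).
#' @param top_n genes kept per coarse type.
#' @return named list of character vectors (one per coarse type).
#' @export
benchmark_marker_sets <- function(marker_stats, top_n = 100L) {
  if (is.list(marker_stats) && !is.data.frame(marker_stats) &&
      !is.null(marker_stats$stats)) {
    marker_stats <- marker_stats$stats
  }
  passing <- marker_stats[marker_stats$marker, , drop = FALSE]
  types <- sort(unique(passing$coarse))
  out <- list()
  for (ct in types) {
    sub <- passing[passing$coarse == ct, , drop = FALSE]
    # a gene may mark several fine states of one coarse type; keep its best
    sub <- sub[order(-sub$min_lfc, sub$gene), , drop = FALSE]
    sub <- sub[!duplicated(sub$gene), , drop = FALSE]
    if (nrow(sub) < 2) {
      .fail("benchmark_marker_sets",
            sprintf("coarse type '%s' has < 2 passing genes", ct))
    }
    if (nrow(sub) < top_n) {
      warning(sprintf(
        "benchmark_marker_sets: '%s' has only %d passing genes (< %d)",
        ct, nrow(sub), top_n))
    }
    out[[ct]] <- sub$gene[seq_len(min(top_n, nrow(sub)))]
  }
  out
}

#' One-sided paired t-test on autocorrelation Z-scores
#'
#' Paired t on `z_deconv - z_raw` with the configured one-sided alternative
#' (`"greater"`: deconvolved larger). Zero-variance differences are guarded:
#' p is reported as 0 or 1 according to the sign of the mean difference
#' (0.5 at exactly zero), with a warning.
#'
#' @param z_deconv,z_raw aligned numeric vectors (n >= 2).
#' @param direction `"greater"` or `"less"` (alternative for the
#'   deconvolved-minus-raw difference).
#' @return list with `t`, `p`, `mean_delta`, `n`, `direction`.
#' @export
paired_autocorr_test <- function(z_deconv, z_raw,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  .assert(length(z_deconv) == length(z_raw) && length(z_deconv) >= 2,
          "paired_autocorr_test", "need aligned vectors with n >= 2")
  d <- z_deconv - z_raw
  if (sd(d) == 0) {
    warning("paired_autocorr_test: zero-variance differences")
    md <- mean(d)
    p <- if (md == 0) 0.5
         else if ((md > 0) == (direction == "greater")) 0 else 1
    return(list(t = NA_real_, p = p, mean_delta = md, n = length(d),
                direction = direction))
  }
  tt <- t.test(z_deconv, z_raw, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), p = tt$p.value, mean_delta = mean(d),
       n = length(d), direction = direction)
}

#' Category-wise paired tests on |Z| of pairwise local correlations
#'
#' Bins gene pairs into tumor-tumor, tumor-nontumor and nontumor-nontumor
#' categories (no self pairs) and runs one-sided paired t-tests on the
#' absolute local-correlation Z-scores: the deconvolved workflow is expected
#' to increase |Z| for tumor-tumor pairs and decrease it for the two
#' categories involving non-tumor markers.
#'
#' @param localcorr_deconv,localcorr_raw `local_corr` objects (or plain
#'   symmetric Z matrices) over a shared gene set.
#' @param tumor_markers,nontumor_markers marker gene vectors (disjoint).
#' @return data frame with one row per category: `category`, `n_pairs`,
#'   `mean_delta_absZ`, `t`, `p`, `direction`.
#' @export
paircorr_category_test <- function(localcorr_deconv, localcorr_raw,
                                   tumor_markers, nontumor_markers) {
  Zd <- if (inherits(localcorr_deconv, "local_corr")) localcorr_deconv$Z
        else localcorr_deconv
  Zr <- if (inherits(localcorr_raw, "local_corr")) localcorr_raw$Z
        else localcorr_raw
  genes <- intersect(rownames(Zd), rownames(Zr))
  tm <- intersect(tumor_markers, genes)
  nm <- setdiff(intersect(nontumor_markers, genes), tm)
  cats <- list(
    `tumor-tumor` = list(a = tm, b = tm, direction = "greater"),
    `tumor-nontumor` = list(a = tm, b = nm, direction = "less"),
    `nontumor-nontumor` = list(a = nm, b = nm, direction = "less"))
  rows <- NULL
  for (nmv in names(cats)) {
    cc <- cats[[nmv]]
    prs <- .gene_pairs(cc$a, cc$b)
    if (nrow(prs) == 0) {
      warning(sprintf("paircorr_category_test: empty category '%s'", nmv))
      next
    }
    vd <- abs(Zd[cbind(prs[, 1], prs[, 2])])
    vr <- abs(Zr[cbind(prs[, 1], prs[, 2])])
    res <- paired_autocorr_test(vd, vr, direction = cc$direction)
    rows <- rbind(rows, data.frame(
      category = nmv, n_pairs = nrow(prs),
      mean_delta_absZ = res$mean_delta, t = res$t, p = res$p,
      direction = cc$direction, stringsAsFactors = FALSE))
  }
  rows
}

.gene_pairs <- function(a, b) {
  if (identical(a, b)) {
    if (length(a) < 2) return(matrix(character(0), ncol = 2))
    idx <- utils::combn(length(a), 2)
    cbind(a[idx[1, ]], a[idx[2, ]])
  } else {
    as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
  }
}

#' Bulk expression contrast of gene signatures between two groups
#'
#' Per gene: `log2((mean expression in group A + 1) / (mean expression in
#' group B + 1))` and a two-sided Wilcoxon rank-sum test across samples
#' (exact for small groups, normal approximation with continuity correction
#' otherwise). Per gene set: the same rank-sum test on per-sample mean
#' expression over the set's genes.
#'
#' @param bulk_expr gene x sample expression matrix (linear scale).
#' @param group_labels per-sample factor with exactly two levels; the first
#'   level is the contrast numerator (group A).
#' @param gene_sets named list of gene sets (genes absent from the matrix
#'   are dropped with a message).
#' @return list with `per_gene` (data frame: gene, set, lfc, p) and
#'   `per_set` (data frame: set, n_genes, mean_lfc, p).
#' @export
bulk_signature_contrast <- function(bulk_expr, group_labels, gene_sets) {
  group_labels <- as.factor(group_labels)
  .assert(nlevels(group_labels) == 2, "bulk_signature_contrast",
          "exactly two groups required")
  .assert(length(group_labels) == ncol(bulk_expr),
          "bulk_signature_contrast", "labels must align with samples")
  if (min(table(group_labels)) < 5) {
    warning("bulk_signature_contrast: a group has < 5 samples")
  }
  ia <- group_labels == levels(group_labels)[1]
  per_gene <- NULL
  per_set <- NULL
  for (set_name in names(gene_sets)) {
    genes <- gene_sets[[set_name]]
    present <- intersect(genes, rownames(bulk_expr))
    if (length(present) < length(genes)) {
      message(sprintf("bulk_signature_contrast: %d/%d genes of '%s' absent, dropped",
                      length(genes) - length(present), length(genes),
                      set_name))
    }
    if (!length(present)) next
    sub <- bulk_expr[present, , drop = FALSE]
    lfc <- log2((rowMeans(sub[, ia, drop = FALSE]) + 1) /
                  (rowMeans(sub[, !ia, drop = FALSE]) + 1))
    pg <- vapply(present, function(g) {
      suppressWarnings(
        wilcox.test(sub[g, ia], sub[g, !ia], alternative = "two.sided")$p.value)
    }, numeric(1))
    per_gene <- rbind(per_gene, data.frame(
      gene = present, set = set_name, lfc = unname(lfc), p = unname(pg),
      stringsAsFactors = FALSE))
    set_score <- colMeans(sub)
    ps <- suppressWarnings(
      wilcox.test(set_score[ia], set_score[!ia],
                  alternative = "two.sided")$p.value)
    per_set <- rbind(per_set, data.frame(
      set = set_name, n_genes = length(present), mean_lfc = mean(lfc),
      p = ps, stringsAsFactors = FALSE))
  }
  list(per_gene = per_gene, per_set = per_set)
}
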