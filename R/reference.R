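# Reference preparation: QC filters, log2 counts-per-10k normalisation,
# pairwise-t marker selection with coarse/fine label handling, and the
# per-state reference profile used for deconvolution.

#' Filter low-quality cells from a reference count matrix
#'
#' Removes cells with fewer than `min_genes` detected genes, fewer than
#' `min_umis` total counts, or a mitochondrial count fraction above
#' `max_mito_frac`. All thresholds are read strictly: a cell with exactly
#' `min_genes` genes, exactly `min_umis` UMIs or a mitochondrial fraction
#' exactly equal to `max_mito_frac` is retained.
#'
#' @param counts cell x gene count matrix.
#' @param min_genes,min_umis,max_mito_frac QC thresholds.
#' @param mito_genes character vector of mitochondrial gene names (may be
#'   empty, e.g. for synthetic data).
#' @return the filtered cell x gene matrix.
#' @export
filter_reference_cells <- function(counts, min_genes = 200L,
                                   min_umis = 1000L, max_mito_frac = 0.10,
                                   mito_genes = character(0)) {
  detected <- rowSums(counts > 0)
  total <- rowSums(counts)
  mito <- intersect(mito_genes, colnames(counts))
  mito_frac <- if (length(mito)) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(total, 1)
  } else rep(0, nrow(counts))
  keep <- detected >= min_genes & total >= min_umis & mito_frac <= max_mito_frac
  if (!any(keep)) {
    failing <- c(
      if (all(detected < min_genes)) "min_genes",
      if (all(total < min_umis)) "min_umis",
      if (all(mito_frac > max_mito_frac)) "max_mito_frac")
    if (!length(failing)) failing <- "combined cell filters"
    .fail("filter_reference_cells",
          sprintf("no cells pass (failing filter: %s)",
                  paste(failing, collapse = ", ")))
  }
  counts[keep, , drop = FALSE]
}

#' Filter genes from a reference count matrix
#'
#' Keeps genes detected in at least `min_cells` cells ("fewer than 3 cells"
#' removes only genes seen in 0-2 cells) and not belonging to any drop set
#' (e.g. mitochondrial or ribosomal protein gene lists).
#'
#' @param counts cell x gene count matrix.
#' @param min_cells minimum number of detecting cells.
#' @param drop_sets named list of gene-name vectors to exclude.
#' @return the filtered matrix (possibly with zero genes; callers validate).
#' @export
filter_reference_genes <- function(counts, min_cells = 3L,
                                   drop_sets = list()) {
  detected <- colSums(counts > 0)
  dropped <- unique(unlist(drop_sets))
  keep <- detected >= min_cells & !(colnames(counts) %in% dropped)
  counts[, keep, drop = FALSE]
}

#' Log2 counts-per-10k normalisation
#'
#' `log2(count / cell_total * 1e4 + 1)` per cell.
#'
#' @param counts cell x gene count matrix with positive cell totals.
#' @return normalized matrix of the same shape.
#' @export
normalize_log2_cp10k <- function(counts) {
  total <- rowSums(counts)
  if (any(total <= 0)) {
    .fail("normalize_log2_cp10k",
          sprintf("%d cell(s) with zero total counts", sum(total <= 0)))
  }
  log2(counts / total * 1e4 + 1)
}

#' Select deconvolution marker genes by pairwise differential tests
#'
#' For every fine state, Welch t-tests on log-normalised expression against
#' each comparison state, with per-pair log2 fold changes computed on
#' linear-scale counts-per-10k means: `log2((mean_A + 1)/(mean_B + 1))`.
#' Non-tumor states are compared against every other state; tumor states
#' (those whose coarse label is `"tumor"`) skip tumor-vs-tumor pairs and are
#' compared against non-tumor states only. A gene is a marker of a state iff
#' its maximum pairwise p-value is below `p_max` and its minimum pairwise
#' log2 fold change exceeds `lfc_min`.
#'
#' @param norm_expr cell x gene log-normalised matrix
#'   (see [normalize_log2_cp10k()]).
#' @param fine_labels per-cell fine state labels (>= 2 cells per state).
#' @param coarse_labels named map state -> coarse type, or a per-cell vector
#'   aligned with `fine_labels`; tumor states must map to `"tumor"`.
#' @param p_max,lfc_min selection thresholds (strict inequalities).
#' @return list with `stats` (data frame: gene, state, coarse, max_p,
#'   min_lfc, marker flag), `markers` (per-fine-state gene sets),
#'   `markers_coarse` (unions per coarse type), and `universe` (union of all
#'   marker sets).
#' @export
select_markers <- function(norm_expr, fine_labels, coarse_labels,
                           p_max = 0.01, lfc_min = 0.1) {
  states <- sort(unique(fine_labels))
  n_per <- table(fine_labels)
  if (any(n_per < 2)) {
    .fail("select_markers", sprintf("state(s) with < 2 cells: %s",
          paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  coarse_map <- .coarse_map(coarse_labels, fine_labels, states)

  G <- ncol(norm_expr)
  lin <- 2^norm_expr - 1  # back to linear-scale cp10k
  mean_log <- rowsum(norm_expr, fine_labels) / as.vector(n_per[states])
  mean_lin <- rowsum(lin, fine_labels) / as.vector(n_per[states])
  var_log <- rowsum(norm_expr^2, fine_labels) / as.vector(n_per[states]) -
    mean_log^2
  # unbiased variance
  var_log <- var_log * as.vector(n_per[states]) / pmax(as.vector(n_per[states]) - 1, 1)

  welch_p <- function(a, b) {
    na <- n_per[[a]]; nb <- n_per[[b]]
    se2 <- var_log[a, ] / na + var_log[b, ] / nb
    tstat <- (mean_log[a, ] - mean_log[b, ]) / sqrt(pmax(se2, .Machine$double.eps))
    df <- se2^2 / pmax((var_log[a, ] / na)^2 / (na - 1) +
                         (var_log[b, ] / nb)^2 / (nb - 1),
                       .Machine$double.eps)
    df <- pmax(df, 1)
    2 * pt(-abs(tstat), df)
  }

  stats <- NULL
  markers <- list()
  for (s in states) {
    others <- setdiff(states, s)
    if (coarse_map[[s]] == "tumor") {
      others <- others[vapply(others, function(o) coarse_map[[o]] != "tumor",
                              logical(1))]
    }
    if (!length(others)) {
      .fail("select_markers",
            sprintf("state '%s' has no comparison states", s))
    }
    pmat <- vapply(others, function(o) welch_p(s, o), numeric(G))
    lfcmat <- vapply(others, function(o) {
      log2((mean_lin[s, ] + 1) / (mean_lin[o, ] + 1))
    }, numeric(G))
    if (length(others) == 1L) {
      max_p <- as.vector(pmat); min_lfc <- as.vector(lfcmat)
    } else {
      max_p <- apply(pmat, 1, max)
      min_lfc <- apply(lfcmat, 1, min)
    }
    is_marker <- max_p < p_max & min_lfc > lfc_min
    markers[[s]] <- colnames(norm_expr)[is_marker]
    stats <- rbind(stats, data.frame(
      gene = colnames(norm_expr), state = s, coarse = coarse_map[[s]],
      max_p = max_p, min_lfc = min_lfc, marker = is_marker,
      stringsAsFactors = FALSE, row.names = NULL))
  }
  coarse_types <- unique(unlist(coarse_map))
  markers_coarse <- lapply(setNames(coarse_types, coarse_types), function(ct) {
    sts <- states[vapply(states, function(s) coarse_map[[s]] == ct, logical(1))]
    sort(unique(unlist(markers[sts])))
  })
  list(stats = stats, markers = markers, markers_coarse = markers_coarse,
       universe = sort(unique(unlist(markers))))
}

.coarse_map <- function(coarse_labels, fine_labels, states) {
  if (!is.null(names(coarse_labels)) &&
      all(states %in% names(coarse_labels))) {
    as.list(coarse_labels[states])
  } else {
    .assert(length(coarse_labels) == length(fine_labels), "select_markers",
            "coarse_labels must be named by state or aligned per cell")
    m <- tapply(coarse_labels, fine_labels, function(x) unique(x)[1])
    as.list(m[states])
  }
}

#' Build a per-state reference expression profile
#'
#' Profile row k is the per-gene mean raw count over state-k cells, floored
#' at `pseudo_min` (default 0: genes with zero count keep probability 0, no
#' pseudocount), restricted to `universe` when given, then normalised to a
#' probability vector.
#'
#' @param counts cell x gene count matrix (already filtered).
#' @param fine_labels per-cell state labels covering all cells.
#' @param pseudo_min numeric floor for profile entries.
#' @param coarse_labels optional state -> coarse map retained on the object.
#' @param universe optional gene subset (e.g. the marker-gene union).
#' @param marker_genes optional per-coarse-type marker sets retained on the
#'   object.
#' @return A `reference_profile` object: `profile` (state x gene, rows sum
#'   to 1), `fine_labels`, `coarse_labels`, `marker_genes`, `pseudo_min`.
#' @export
build_reference <- function(counts, fine_labels, pseudo_min = 0,
                            coarse_labels = NULL, universe = NULL,
                            marker_genes = NULL) {
  .assert(length(fine_labels) == nrow(counts), "build_reference",
          "labels must cover all cells")
  states <- sort(unique(fine_labels))
  n_per <- table(fine_labels)
  mean_cnt <- rowsum(.as_matrix(counts), fine_labels) / as.vector(n_per[states])
  mean_cnt <- pmax(mean_cnt, pseudo_min)
  if (!is.null(universe)) {
    missing <- setdiff(universe, colnames(mean_cnt))
    .assert(length(missing) == 0, "build_reference",
            sprintf("universe genes absent from counts: %s",
                    paste(head(missing, 5), collapse = ", ")))
    mean_cnt <- mean_cnt[, universe, drop = FALSE]
  }
  rs <- rowSums(mean_cnt)
  if (any(rs <= 0)) {
    .fail("build_reference",
          sprintf("state(s) with zero total expression over the gene universe: %s",
                  paste(states[rs <= 0], collapse = ", ")))
  }
  prof <- mean_cnt / rs
  structure(list(profile = prof, fine_labels = states,
                 coarse_labels = coarse_labels, marker_genes = marker_genes,
                 pseudo_min = pseudo_min),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: %d states x %d genes (pseudo_min = %g)\n",
              nrow(x$profile), ncol(x$profile), x$pseudo_min))
  if (!is.null(x$coarse_labels)) {
    tab <- table(unlist(x$coarse_labels))
    cat("  coarse types:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
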