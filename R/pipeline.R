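# Pipeline configuration and the end-to-end composition:
# reference prep -> deconvolution -> tumor counts -> spatial modules ->
# subsampling consensus -> deconvolved-vs-raw benchmark.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its default, plus
#' optional input paths. Configurations round-trip losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param reference_dir,spatial_dir,positions_path,samples_path,tf_list_path
#'   optional input paths; when `NULL`, [run_pipeline()] simulates its
#'   inputs from `sim` instead.
#' @param min_genes,min_umis,max_mito reference cell QC thresholds.
#' @param gene_min_cells reference gene filter (detected in >= this many
#'   cells).
#' @param marker_p_max,marker_lfc_min marker-selection thresholds.
#' @param pseudo_min reference profile floor.
#' @param min_spot_genes,min_spot_umis,gene_min_spots_exclusive spatial
#'   filters.
#' @param k kNN graph neighbors.
#' @param fdr_autocorr,top_n module-gene selection.
#' @param min_gene_threshold,module_fdr,core_only module detection.
#' @param subsample_fraction,n_reps,consensus_threshold consensus stage.
#' @param benchmark_top_n markers per cell type for benchmarking.
#' @param n_perm permutations for the spatial statistics.
#' @param master_seed master seed; per-stage seeds derive from it.
#' @param sim optional [sim_config()] used when paths are `NULL`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reference_dir = NULL, spatial_dir = NULL,
                            positions_path = NULL, samples_path = NULL,
                            tf_list_path = NULL,
                            min_genes = 200L, min_umis = 1000L,
                            max_mito = 0.10, gene_min_cells = 3L,
                            marker_p_max = 0.01, marker_lfc_min = 0.1,
                            pseudo_min = 0,
                            min_spot_genes = 1000L, min_spot_umis = 1000L,
                            gene_min_spots_exclusive = 3L,
                            k = 6L, fdr_autocorr = 0.01, top_n = 500L,
                            min_gene_threshold = 15L, module_fdr = 0.05,
                            core_only = TRUE,
                            subsample_fraction = 0.6, n_reps = 100L,
                            consensus_threshold = 0.8,
                            benchmark_top_n = 100L, n_perm = 1000L,
                            master_seed = 1L, sim = NULL) {
  cfg <- list(
    reference_dir = reference_dir, spatial_dir = spatial_dir,
    positions_path = positions_path, samples_path = samples_path,
    tf_list_path = tf_list_path,
    min_genes = as.integer(min_genes), min_umis = as.integer(min_umis),
    max_mito = max_mito, gene_min_cells = as.integer(gene_min_cells),
    marker_p_max = marker_p_max, marker_lfc_min = marker_lfc_min,
    pseudo_min = pseudo_min,
    min_spot_genes = as.integer(min_spot_genes),
    min_spot_umis = as.integer(min_spot_umis),
    gene_min_spots_exclusive = as.integer(gene_min_spots_exclusive),
    k = as.integer(k), fdr_autocorr = fdr_autocorr,
    top_n = as.integer(top_n),
    min_gene_threshold = as.integer(min_gene_threshold),
    module_fdr = module_fdr, core_only = isTRUE(core_only),
    subsample_fraction = subsample_fraction, n_reps = as.integer(n_reps),
    consensus_threshold = consensus_threshold,
    benchmark_top_n = as.integer(benchmark_top_n),
    n_perm = as.integer(n_perm), master_seed = as.integer(master_seed))
  cfg$sim <- sim
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stage <- "pipeline_config"
  .assert(cfg$max_mito >= 0 && cfg$max_mito <= 1, stage, "max_mito in [0,1]")
  .assert(cfg$marker_p_max > 0 && cfg$marker_p_max <= 1, stage,
          "marker_p_max in (0,1]")
  .assert(cfg$subsample_fraction > 0 && cfg$subsample_fraction < 1, stage,
          "subsample_fraction in (0,1)")
  .assert(cfg$consensus_threshold >= 0 && cfg$consensus_threshold <= 1,
          stage, "consensus_threshold in [0,1]")
  .assert(cfg$fdr_autocorr > 0 && cfg$fdr_autocorr <= 1, stage,
          "fdr_autocorr in (0,1]")
  .assert(cfg$module_fdr > 0 && cfg$module_fdr <= 1, stage,
          "module_fdr in (0,1]")
  .assert(cfg$k >= 1 && cfg$top_n >= 1 && cfg$n_reps >= 0 &&
            cfg$n_perm >= 1, stage, "k, top_n, n_reps, n_perm ranges")
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @rdname pipeline_config_io
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- if (!is.null(cfg$sim)) {
    s <- unclass(cfg$sim)
    s$region_map <- list(values = as.vector(s$region_map),
                         nrow = nrow(s$region_map))
    s
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(x$sim)) {
    s <- x$sim
    rm_ <- matrix(unlist(s$region_map$values), nrow = s$region_map$nrow,
                  byrow = FALSE)
    sim <- sim_config(
      n_genes = s$n_genes, n_states = s$n_states,
      tumor_state_ids = unlist(s$tumor_state_ids),
      stromal_state_ids = unlist(s$stromal_state_ids),
      markers_per_state = s$markers_per_state, marker_fold = s$marker_fold,
      grid_rows = s$grid_rows, grid_cols = s$grid_cols,
      region_map = rm_,
      fraction_params = lapply(s$fraction_params, unlist),
      depth_mean = s$depth_mean, depth_dispersion = s$depth_dispersion,
      module_specs = lapply(s$module_specs, function(m) {
        m$genes <- unlist(m$genes)
        if (!is.null(m$center)) m$center <- unlist(m$center)
        m
      }),
      n_samples = s$n_samples, n_slides = s$n_slides,
      cells_per_state = s$cells_per_state, seed = s$seed)
  }
  x$sim <- NULL
  cfg <- do.call(pipeline_config, x)
  cfg$sim <- sim
  cfg
}

#' Run the full workflow
#'
#' Executes reference preparation, spot/gene filtering, deconvolution,
#' tumor-count extraction, spatial module detection, subsampling consensus
#' and the deconvolved-vs-raw benchmark, logging before/after counts per
#' filter. When `out_dir` is given, writes every stage's tables plus a
#' manifest JSON (config, seeds, per-stage dimensions).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage's result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("prismspot")),
                   r_version = R.version.string,
                   master_seed = config$master_seed,
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    say("[%s] %s", name, paste(names(list(...)), unlist(list(...)),
                               sep = "=", collapse = " "))
  }

  # --- inputs -------------------------------------------------------------
  if (is.null(config$reference_dir)) {
    sim <- config$sim
    if (is.null(sim)) sim <- sim_config(seed = config$master_seed)
    ref_sim <- simulate_reference(sim, seed = derive_seed(config$master_seed, 1L))
    tissue <- simulate_tissue(sim, seed = derive_seed(config$master_seed, 2L))
    ref_counts <- ref_sim$counts
    fine <- ref_sim$fine_labels
    coarse <- ref_sim$coarse_labels
    spots <- tissue$dataset
    truth <- tissue$truth
    tf_list <- truth$tf_list
    mito_genes <- character(0)
    drop_sets <- list()
  } else {
    rc <- read_counts_mtx(config$reference_dir)
    labels <- read.table(file.path(config$reference_dir, "labels.tsv"),
                         sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
    idx <- match(rownames(rc$counts), labels$barcode)
    fine <- labels$fine_label[idx]
    coarse <- labels$coarse_label[idx]
    ref_counts <- .as_matrix(rc$counts)
    spots <- read_spot_dataset(config$spatial_dir, config$positions_path,
                               config$samples_path)
    truth <- NULL
    tf_list <- read_gene_list(config$tf_list_path)
    mito_genes <- grep("^mt-", colnames(ref_counts), value = TRUE,
                       ignore.case = TRUE)
    drop_sets <- list(mito = mito_genes,
                      ribo = grep("^Rp[sl]", colnames(ref_counts),
                                  value = TRUE, ignore.case = TRUE))
  }

  # --- stage 1: reference preparation ------------------------------------
  n0 <- nrow(ref_counts)
  cells <- filter_reference_cells(ref_counts, config$min_genes,
                                  config$min_umis, config$max_mito,
                                  mito_genes)
  fine <- fine[match(rownames(cells), rownames(ref_counts))]
  coarse <- coarse[match(rownames(cells), rownames(ref_counts))]
  g0 <- ncol(cells)
  cells <- filter_reference_genes(cells, config$gene_min_cells, drop_sets)
  norm <- normalize_log2_cp10k(cells)
  coarse_map <- tapply(coarse, fine, function(x) unique(x)[1])
  mk <- select_markers(norm, fine, coarse_map,
                       p_max = config$marker_p_max,
                       lfc_min = config$marker_lfc_min)
  ref <- build_reference(cells, fine, pseudo_min = config$pseudo_min,
                         coarse_labels = as.list(coarse_map),
                         universe = mk$universe,
                         marker_genes = mk$markers_coarse)
  log_stage("prep_ref", cells_in = n0, cells_kept = nrow(cells),
            genes_in = g0, genes_kept = ncol(cells),
            marker_universe = length(mk$universe))

  # --- stage 2: spot filtering + deconvolution ---------------------------
  s0 <- nrow(spots$counts)
  spots_f <- filter_spots_and_genes(spots, config$min_spot_genes,
                                    config$min_spot_umis,
                                    config$gene_min_spots_exclusive)
  dec <- deconvolve(spots_f, ref)
  log_stage("deconvolve", spots_in = s0, spots_kept = nrow(spots_f$counts),
            genes_used = length(dec$genes),
            states = length(dec$states))

  # --- stage 3: tumor counts + spatial modules ---------------------------
  tumor_states <- names(which(unlist(ref$coarse_labels) == "tumor"))
  tum <- tumor_counts(dec, tumor_states)
  log_stage("tumor_counts", tumor_states = length(tumor_states),
            total_tumor_reads = sum(tum))
  graph <- build_knn_graph(dec$spots$positions,
                           paste(dec$spots$samples$sample_id,
                                 dec$spots$samples$slide_id),
                           k = config$k)
  nz <- colSums(tum) > 0
  resid <- standardized_residuals(tum[, nz, drop = FALSE], rowSums(tum))
  acorr <- autocorrelation(resid, graph, n_perm = config$n_perm,
                           seed = derive_seed(config$master_seed, 3L))
  sel <- select_module_genes(acorr, tf_list,
                             fdr_max = config$fdr_autocorr,
                             top_n = config$top_n)
  if (length(sel) >= 2) {
    lc <- local_correlation(resid, graph, sel, n_perm = config$n_perm,
                            seed = derive_seed(config$master_seed, 4L))
    mods <- detect_modules(lc, config$min_gene_threshold,
                           config$module_fdr, config$core_only)
  } else {
    lc <- NULL
    mods <- structure(list(assignment = setNames(rep(-1L, length(sel)), sel),
                           modules = list(), z_threshold = NA_real_),
                      class = "module_result")
  }
  scores <- if (length(mods$modules)) {
    tt <- rowSums(tum)
    ntum <- matrix(0, nrow(tum), ncol(tum), dimnames = dimnames(tum))
    pos <- tt > 0
    ntum[pos, ] <- log2(tum[pos, , drop = FALSE] / tt[pos] * 1e4 + 1)
    module_scores(ntum, mods, graph)
  }
  log_stage("modules", genes_tested = sum(nz), genes_selected = length(sel),
            n_modules = length(mods$modules),
            genes_assigned = sum(mods$assignment != -1L))

  # --- stage 4: consensus -------------------------------------------------
  consensus <- if (config$n_reps > 0 && length(mods$modules)) {
    run_consensus(tum, graph, sel, mods,
                  n_reps = config$n_reps,
                  fraction = config$subsample_fraction,
                  threshold = config$consensus_threshold,
                  n_perm = config$n_perm,
                  master_seed = derive_seed(config$master_seed, 5L),
                  min_gene_threshold = config$min_gene_threshold,
                  fdr_threshold = config$module_fdr,
                  core_only = config$core_only)
  }
  log_stage("consensus", n_reps = config$n_reps,
            n_selected = if (!is.null(consensus))
              length(consensus$selected_genes) else 0L)

  # --- stage 5: benchmark -------------------------------------------------
  bench <- benchmark_deconv_vs_raw(dec, tum, graph, mk,
                                   top_n = config$benchmark_top_n,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(config$master_seed, 6L))
  log_stage("benchmark",
            celltypes = nrow(bench$autocorr_tests),
            categories = nrow(bench$paircorr_tests))

  results <- list(reference = ref, markers = mk, deconv = dec,
                  tumor_counts = tum, graph = graph, autocorr = acorr,
                  selected_genes = sel, local_corr = lc, modules = mods,
                  module_scores = scores, consensus = consensus,
                  benchmark = bench, truth = truth, manifest = manifest)

  # --- stage 6: artifacts -------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(dec$theta, file.path(out_dir, "theta.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write_counts_mtx(tum, file.path(out_dir, "tumor_counts"))
    write.table(acorr, file.path(out_dir, "autocorrelation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = names(mods$assignment),
                           module = mods$assignment),
                file.path(out_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(scores)) {
      write.table(scores, file.path(out_dir, "module_scores.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
    if (!is.null(consensus)) {
      write.table(data.frame(gene = names(consensus$gene_consensus),
                             consensus = consensus$gene_consensus,
                             selected = names(consensus$gene_consensus) %in%
                               consensus$selected_genes),
                  file.path(out_dir, "consensus.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(consensus$replicate_assignments,
                  file.path(out_dir, "replicate_assignments.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
    jsonlite::write_json(
      list(autocorr_tests = bench$autocorr_tests,
           paircorr_tests = bench$paircorr_tests),
      file.path(out_dir, "benchmark.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages <- manifest$stages
    results$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}

#' Benchmark the deconvolved workflow against raw counts
#'
#' Runs the autocorrelation and local-correlation statistics on both the
#' deconvolved tumor counts and the raw counts (over the shared gene
#' universe and the same graph), then applies the one-sided paired tests
#' over cell-type marker sets: tumor markers are expected to gain
#' autocorrelation Z under deconvolution, non-tumor markers to lose it; the
#' pairwise |Z| categories follow the tumor-tumor up / others down
#' directions.
#'
#' @param dec a `spot_deconv`.
#' @param tum tumor-specific counts from [tumor_counts()].
#' @param graph the neighbor graph.
#' @param markers a [select_markers()] result.
#' @param top_n markers per coarse type.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `marker_sets`, `autocorr_tests` (per coarse type),
#'   `paircorr_tests` (per category), and the per-gene Z tables
#'   (`z_deconv`, `z_raw`).
#' @export
benchmark_deconv_vs_raw <- function(dec, tum, graph, markers,
                                    top_n = 100L, n_perm = 500L,
                                    seed = 1L) {
  sets <- benchmark_marker_sets(markers, top_n = top_n)
  raw <- .as_matrix(dec$spots$counts)
  # residuals only over the benchmarked genes; depths come from the full
  # matrices, so the per-gene statistics are unchanged by the restriction
  needed <- intersect(unique(unlist(sets)), colnames(tum))
  nz <- needed[colSums(tum[, needed, drop = FALSE]) > 0 &
                 colSums(raw[, needed, drop = FALSE]) > 0]
  rd <- standardized_residuals(tum[, nz, drop = FALSE], rowSums(tum))
  rr <- standardized_residuals(raw[, nz, drop = FALSE], rowSums(raw))
  # common permutation stream for both workflows: the Monte-Carlo error of
  # the two Z estimates is positively correlated and partially cancels in
  # the paired differences (common-random-numbers design)
  ad <- autocorrelation(rd, graph, n_perm = n_perm, seed = derive_seed(seed, 1L))
  ar <- autocorrelation(rr, graph, n_perm = n_perm, seed = derive_seed(seed, 1L))
  zd <- setNames(ad$Z, ad$gene)
  zr <- setNames(ar$Z, ar$gene)

  tumor_set <- intersect(sets[["tumor"]], names(zd))
  rows <- NULL
  for (ct in names(sets)) {
    g <- intersect(sets[[ct]], names(zd))
    if (length(g) < 2) {
      warning(sprintf("benchmark: cell type '%s' has < 2 usable markers", ct))
      next
    }
    dirn <- if (ct == "tumor") "greater" else "less"
    res <- paired_autocorr_test(zd[g], zr[g], direction = dirn)
    rows <- rbind(rows, data.frame(
      celltype = ct, n_genes = length(g), mean_delta_z = res$mean_delta,
      t = res$t, p = res$p, direction = dirn, stringsAsFactors = FALSE))
  }

  nontumor_set <- setdiff(unlist(sets[names(sets) != "tumor"]), tumor_set)
  nontumor_set <- intersect(nontumor_set, names(zd))
  both <- c(tumor_set, nontumor_set)
  lcd <- local_correlation(rd, graph, both, n_perm = n_perm,
                           seed = derive_seed(seed, 3L))
  lcr <- local_correlation(rr, graph, both, n_perm = n_perm,
                           seed = derive_seed(seed, 3L))
  cat_tests <- paircorr_category_test(lcd, lcr, tumor_set, nontumor_set)
  list(marker_sets = sets, autocorr_tests = rows,
       paircorr_tests = cat_tests, z_deconv = zd, z_raw = zr)
}
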