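# Shared fixtures built in code. Heavy objects are memoised so several test
# files can reuse one default-scale run.

.fixtures <- new.env(parent = emptyenv())

# small 3-state configuration exercising markers + one tumor module
small_config <- function(seed = 1L, marker_fold = 10, n_cells = 200L,
                         amplitude = 3) {
  sim_config(
    n_genes = 60L, n_states = 3L,
    tumor_state_ids = 1L, stromal_state_ids = 2L,
    markers_per_state = 5L, marker_fold = marker_fold,
    grid_rows = 8L, grid_cols = 8L,
    region_map = matrix("NE", 8, 8),
    fraction_params = list(NE = c(4, 2, 2)),
    depth_mean = 1500, depth_dispersion = 0.25,
    module_specs = list(list(component = "tumor", genes = 21:36,
                             field = "gradient", amplitude = amplitude,
                             axis = "col")),
    n_samples = 1L, n_slides = 1L,
    cells_per_state = n_cells, seed = seed)
}

# the package's default study conditions, scaled filters for the 220-gene
# synthetic transcriptome
default_prepped <- function(seed = 1L) {
  key <- paste0("prep", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- sim_config(seed = seed)
  ref <- simulate_reference(cfg, seed = seed + 500L)
  tis <- simulate_tissue(cfg, seed = seed + 900L)
  cells <- filter_reference_cells(ref$counts, min_genes = 50,
                                  min_umis = 500)
  norm <- normalize_log2_cp10k(cells)
  keep <- match(rownames(cells), rownames(ref$counts))
  fine <- ref$fine_labels[keep]
  coarse <- tapply(ref$coarse_labels[keep], fine, function(x) x[1])
  mk <- select_markers(norm, fine, coarse)
  rp <- build_reference(cells, fine, universe = mk$universe,
                        coarse_labels = as.list(coarse),
                        marker_genes = mk$markers_coarse)
  dec <- deconvolve(tis$dataset, rp)
  tum <- tumor_counts(dec, names(which(unlist(rp$coarse_labels) == "tumor")))
  graph <- build_knn_graph(
    dec$spots$positions,
    paste(dec$spots$samples$sample_id, dec$spots$samples$slide_id), k = 6)
  out <- list(cfg = cfg, ref = ref, tis = tis, mk = mk, rp = rp, dec = dec,
              tum = tum, graph = graph)
  .fixtures[[key]] <- out
  out
}

# a tiny hand-made spot dataset over a square lattice, one tissue
toy_spot_dataset <- function(counts, rows, cols, sample_id = "m1",
                             slide_id = "s1") {
  n <- rows * cols
  stopifnot(nrow(counts) == n)
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  bc <- sprintf("%s_%s_r%dc%d", sample_id, slide_id, rr, cc)
  rownames(counts) <- bc
  structure(list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    positions = data.frame(barcode = bc, in_tissue = 1L, array_row = rr,
                           array_col = cc, pxl_row_in_fullres = rr * 100L,
                           pxl_col_in_fullres = cc * 100L),
    samples = data.frame(barcode = bc, sample_id = sample_id,
                         slide_id = slide_id)), class = "spot_dataset")
}

# run reference prep + deconvolution + tumor extraction for any sim config
prep_run <- function(cfg, seed) {
  ref <- simulate_reference(cfg, seed = seed + 500L)
  tis <- simulate_tissue(cfg, seed = seed + 900L)
  cells <- filter_reference_cells(ref$counts, min_genes = 50,
                                  min_umis = 500)
  keep <- match(rownames(cells), rownames(ref$counts))
  fine <- ref$fine_labels[keep]
  coarse <- tapply(ref$coarse_labels[keep], fine, function(x) x[1])
  mk <- select_markers(normalize_log2_cp10k(cells), fine, coarse)
  rp <- build_reference(cells, fine, universe = mk$universe,
                        coarse_labels = as.list(coarse),
                        marker_genes = mk$markers_coarse)
  dec <- deconvolve(tis$dataset, rp)
  tum <- tumor_counts(dec, names(which(unlist(rp$coarse_labels) == "tumor")))
  graph <- build_knn_graph(
    dec$spots$positions,
    paste(dec$spots$samples$sample_id, dec$spots$samples$slide_id), k = 6)
  list(cfg = cfg, tis = tis, mk = mk, rp = rp, dec = dec, tum = tum,
       graph = graph)
}

# spatial module detection on the tumor counts of a prep_run
module_run <- function(pr, seed, n_perm = 250L) {
  resid <- standardized_residuals(pr$tum[, colSums(pr$tum) > 0,
                                         drop = FALSE], rowSums(pr$tum))
  ac <- autocorrelation(resid, pr$graph, n_perm = n_perm, seed = seed)
  sel <- select_module_genes(ac, pr$tis$truth$tf_list)
  lc <- local_correlation(resid, pr$graph, sel, n_perm = n_perm,
                          seed = seed + 1L)
  mods <- detect_modules(lc)
  list(resid = resid, acorr = ac, sel = sel, lc = lc, mods = mods)
}

# adjusted Rand index (mclust's implementation is the independent oracle in
# the acceptance tests; this tiny version serves non-acceptance checks)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
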