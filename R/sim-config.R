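#' Simulation configuration for synthetic spatial transcriptomics data
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reference()] and [simulate_tissue()]. The defaults describe the
#' package's reference synthetic tissue: a 20x20 spot lattice per tissue with
#' four cell states (two tumor states -- a neuroendocrine-like "NE" state and
#' a non-neuroendocrine "nonNE" tumor state -- one stromal and one immune
#' state), state-exclusive marker genes at 8-fold elevation, ~2000 UMIs per
#' spot, three planted tumor-component spatial modules of 20 genes each and
#' one spatially smooth stromal confounder module, laid out as 2 tissues per
#' slide x 2 slides (technical-replicate pairs share region geometry).
#'
#' @param n_genes total number of genes.
#' @param n_states number of reference cell states.
#' @param tumor_state_ids,stromal_state_ids disjoint index sets into
#'   `1:n_states` marking tumor and stromal states.
#' @param markers_per_state number of state-exclusive marker genes per state.
#' @param marker_fold fold elevation of a marker gene in its own state
#'   relative to every other state (> 0).
#' @param grid_rows,grid_cols spot lattice dimensions per tissue.
#' @param region_map character matrix (`grid_rows` x `grid_cols`) assigning a
#'   region label to every lattice position; `NULL` uses the default layout
#'   (left third "NE", right two thirds "nonNE", a central horizontal
#'   "stroma" band overriding both).
#' @param fraction_params named list mapping each region label to a Dirichlet
#'   concentration vector of length `n_states` (all entries > 0).
#' @param depth_mean,depth_dispersion lognormal law for per-spot total UMIs:
#'   `depth_mean` is the mean total, `depth_dispersion` the sdlog.
#' @param module_specs list of planted modules; each element a list with
#'   fields `component` ("tumor" or "stromal"), `genes` (integer gene
#'   indices, >= 15 genes), `field` ("patch" or "gradient"), `amplitude`
#'   (> 0), and optional `center` (c(row, col)), `radius`, `axis`
#'   ("row"/"col"). `NULL` uses the default three tumor modules plus one
#'   stromal confounder.
#' @param n_samples,n_slides replicate layout: `n_samples` tissues per slide
#'   (biological replicates) x `n_slides` slides (technical replicates).
#' @param cells_per_state number of reference cells simulated per state
#'   (>= 20).
#' @param seed integer seed stored with the configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 220L,
                       n_states = 4L,
                       tumor_state_ids = c(1L, 2L),
                       stromal_state_ids = 3L,
                       markers_per_state = 25L,
                       marker_fold = 8,
                       grid_rows = 20L,
                       grid_cols = 20L,
                       region_map = NULL,
                       fraction_params = NULL,
                       depth_mean = 2000,
                       depth_dispersion = 0.3,
                       module_specs = NULL,
                       n_samples = 2L,
                       n_slides = 2L,
                       cells_per_state = 100L,
                       seed = 1L) {
  if (is.null(region_map)) region_map <- default_region_map(grid_rows, grid_cols)
  if (is.null(fraction_params)) {
    fraction_params <- default_fraction_params(n_states, tumor_state_ids,
                                               stromal_state_ids,
                                               rownames_regions = unique(as.vector(region_map)))
  }
  if (is.null(module_specs)) {
    module_specs <- default_module_specs(n_genes, n_states, markers_per_state,
                                         grid_rows, grid_cols)
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_states = as.integer(n_states),
    tumor_state_ids = as.integer(tumor_state_ids),
    stromal_state_ids = as.integer(stromal_state_ids),
    markers_per_state = as.integer(markers_per_state),
    marker_fold = marker_fold,
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    region_map = region_map, fraction_params = fraction_params,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    module_specs = module_specs,
    n_samples = as.integer(n_samples), n_slides = as.integer(n_slides),
    cells_per_state = as.integer(cells_per_state),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stage <- "sim_config"
  .assert(cfg$n_genes >= 1 && cfg$n_states >= 2, stage, "need >= 1 gene and >= 2 states")
  .assert(length(intersect(cfg$tumor_state_ids, cfg$stromal_state_ids)) == 0,
          stage, "tumor and stromal state sets must be disjoint")
  .assert(all(cfg$tumor_state_ids %in% seq_len(cfg$n_states)) &&
            all(cfg$stromal_state_ids %in% seq_len(cfg$n_states)),
          stage, "state ids out of range")
  .assert(cfg$marker_fold > 0, stage, "marker_fold must be > 0")
  .assert(cfg$depth_mean > 0 && cfg$depth_dispersion > 0, stage,
          "depth law parameters must be > 0")
  .assert(cfg$cells_per_state >= 20L, stage, "need >= 20 cells per state")
  .assert(is.matrix(cfg$region_map) &&
            nrow(cfg$region_map) == cfg$grid_rows &&
            ncol(cfg$region_map) == cfg$grid_cols,
          stage, "region_map dimensions must match the lattice")
  regions <- unique(as.vector(cfg$region_map))
  .assert(all(regions %in% names(cfg$fraction_params)), stage,
          "every region needs a Dirichlet concentration vector")
  for (a in cfg$fraction_params) {
    .assert(length(a) == cfg$n_states && all(a > 0), stage,
            "concentrations must be positive and of length n_states")
  }
  for (m in cfg$module_specs) {
    .assert(m$component %in% c("tumor", "stromal"), stage,
            "module component must be 'tumor' or 'stromal'")
    .assert(length(m$genes) >= 15L, stage, "every module needs >= 15 genes")
    .assert(all(m$genes >= 1L & m$genes <= cfg$n_genes), stage,
            "module gene indices out of range")
    .assert(m$amplitude >= 0, stage,
            "module amplitude must be >= 0 (0 = planted null)")
    .assert(m$field %in% c("patch", "gradient"), stage,
            sprintf("unknown field type '%s'", m$field))
  }
  invisible(cfg)
}

default_region_map <- function(rows, cols) {
  m <- matrix("nonNE", rows, cols)
  m[, seq_len(max(1L, floor(cols / 3)))] <- "NE"
  band <- seq(floor(rows * 0.4) + 1L, min(rows, floor(rows * 0.6) + 1L))
  m[band, ] <- "stroma"
  m
}

default_fraction_params <- function(n_states, tumor_ids, stromal_ids,
                                    rownames_regions) {
  ne <- tumor_ids[1]
  nonne <- if (length(tumor_ids) > 1) tumor_ids[2] else tumor_ids[1]
  base <- rep(1, n_states)
  mk <- function(boost_ids, boost) {
    a <- base
    a[boost_ids] <- boost
    a
  }
  # low total concentration = strong spot-level "infiltration" noise;
  # within-tumor composition (NE vs nonNE) carries the smooth regional
  # structure, the stroma band is mild
  out <- list()
  for (r in rownames_regions) {
    out[[r]] <- switch(r,
      NE = { a <- base * 0.55; a[ne] <- 7; a[nonne] <- 0.25
             a[stromal_ids] <- 1.1; a },
      nonNE = { a <- base * 0.55; a[nonne] <- 7; a[ne] <- 0.25
                a[stromal_ids] <- 1.1; a },
      stroma = { a <- base * 1.1; a[ne] <- 1.9; a[nonne] <- 1.9
                 a[stromal_ids] <- 2.2; a },
      rep(2, n_states))
  }
  out
}

# default gene layout: state marker blocks first, then module gene blocks
default_module_specs <- function(n_genes, n_states, markers_per_state,
                                 rows, cols) {
  offset <- n_states * markers_per_state
  need <- offset + 4L * 20L
  if (n_genes < need) {
    .fail("sim_config", sprintf(
      "default module layout needs >= %d genes (got %d); pass module_specs",
      need, n_genes))
  }
  blk <- function(i) offset + (i - 1L) * 20L + seq_len(20L)
  list(
    list(component = "tumor", genes = blk(1), field = "patch",
         amplitude = 4, center = c(ceiling(rows * 0.2), ceiling(cols * 0.2)),
         radius = max(3, floor(min(rows, cols) * 0.2))),
    list(component = "tumor", genes = blk(2), field = "gradient",
         amplitude = 4, axis = "col"),
    list(component = "tumor", genes = blk(3), field = "patch",
         amplitude = 4, center = c(ceiling(rows * 0.8), ceiling(cols * 0.75)),
         radius = max(3, floor(min(rows, cols) * 0.2))),
    list(component = "stromal", genes = blk(4), field = "gradient",
         amplitude = 3, axis = "row")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic spatial transcriptomics configuration\n")
  cat(sprintf("  genes: %d  states: %d (tumor: %s; stromal: %s)\n",
              x$n_genes, x$n_states,
              paste(x$tumor_state_ids, collapse = ","),
              paste(x$stromal_state_ids, collapse = ",")))
  cat(sprintf("  lattice: %dx%d, %d sample(s) x %d slide(s)\n",
              x$grid_rows, x$grid_cols, x$n_samples, x$n_slides))
  cat(sprintf("  depth: lognormal(mean=%g, sdlog=%g); marker fold %g x %d/state\n",
              x$depth_mean, x$depth_dispersion, x$marker_fold,
              x$markers_per_state))
  cat(sprintf("  planted modules: %d (%s)\n", length(x$module_specs),
              paste(vapply(x$module_specs, `[[`, "", "component"),
                    collapse = ", ")))
  invisible(x)
}
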