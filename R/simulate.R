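# Synthetic data generator: reference cells, spatial tissues with planted
# spatially smooth gene modules and a stromal confounder, replicate layout.

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

state_roles <- function(cfg) {
  role <- rep("other", cfg$n_states)
  role[cfg$tumor_state_ids] <- "tumor"
  role[cfg$stromal_state_ids] <- "stromal"
  role
}

state_names <- function(cfg) {
  sprintf("S%02d_%s", seq_len(cfg$n_states), state_roles(cfg))
}

gene_names <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

# state x gene expression probability matrix the generator draws from.
# Marker blocks are state-exclusive; tumor-module genes are elevated in every
# tumor state (so marker selection assigns them to the coarse tumor type) and
# stromal-module genes in every stromal state.
true_profiles <- function(cfg) {
  G <- cfg$n_genes
  K <- cfg$n_states
  n_mark <- K * cfg$markers_per_state
  .assert(G >= n_mark, "true_profiles", "n_genes too small for marker blocks")
  marker_block <- lapply(seq_len(K), function(k) {
    (k - 1L) * cfg$markers_per_state + seq_len(cfg$markers_per_state)
  })
  for (m in cfg$module_specs) {
    if (any(m$genes <= n_mark)) {
      .fail("true_profiles",
            "module genes overlap state-exclusive marker blocks; markers must be state-exclusive")
    }
  }
  base <- with_seed(derive_seed(cfg$seed, 777L), rgamma(G, shape = 2, rate = 2) + 0.1)
  # planted program genes are drawn from the well-expressed end of the
  # transcriptome (modules are only detectable for adequately covered genes)
  boost <- if (is.null(cfg$module_expr_boost)) 2 else cfg$module_expr_boost
  for (m in cfg$module_specs) base[m$genes] <- boost * base[m$genes]
  rates <- matrix(rep(base, each = K), nrow = K)
  for (k in seq_len(K)) rates[k, marker_block[[k]]] <- cfg$marker_fold * base[marker_block[[k]]]
  for (m in cfg$module_specs) {
    ids <- if (m$component == "tumor") cfg$tumor_state_ids else cfg$stromal_state_ids
    rates[ids, m$genes] <- cfg$marker_fold * rates[ids, m$genes]
  }
  prof <- rates / rowSums(rates)
  dimnames(prof) <- list(state_names(cfg), gene_names(cfg))
  attr(prof, "state_mass") <- rowSums(rates)
  prof
}

marker_gene_ids <- function(cfg) {
  lapply(seq_len(cfg$n_states), function(k) {
    (k - 1L) * cfg$markers_per_state + seq_len(cfg$markers_per_state)
  })
}

#' Simulate a single-cell reference with state-exclusive markers
#'
#' Draws `cells_per_state` cells per state with lognormal library sizes and
#' multinomial gene counts from the configured state profiles. Marker genes
#' are elevated `marker_fold`-fold in their own state, so their mean
#' expression exceeds that in any other state in expectation.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return A list with `counts` (cell x gene integer matrix), `fine_labels`
#'   and `coarse_labels` (per cell; tumor states collapse to `"tumor"`),
#'   and `profiles` (the true state x gene probability matrix).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  validate_sim_config(config)
  prof <- true_profiles(config)
  K <- config$n_states
  n <- config$cells_per_state
  roles <- state_roles(config)
  fine <- rep(state_names(config), each = n)
  coarse <- rep(ifelse(roles == "tumor", "tumor", roles), each = n)
  # cells of states with larger transcriptional mass (big marker/module
  # programs) carry proportionally larger libraries, so per-gene raw mean
  # expression keeps the configured fold ratios across states
  mass <- attr(prof, "state_mass")
  depth_scale <- mass / mean(mass)
  counts <- with_seed(seed, {
    depth <- pmax(100L, round(rep(depth_scale, each = n) * rlnorm(K * n,
      meanlog = log(config$depth_mean) - config$depth_dispersion^2 / 2,
      sdlog = config$depth_dispersion)))
    out <- matrix(0L, nrow = K * n, ncol = config$n_genes)
    for (i in seq_len(K * n)) {
      k <- (i - 1L) %/% n + 1L
      out[i, ] <- as.integer(rmultinom(1, depth[i], prof[k, ]))
    }
    out
  })
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(nrow(counts))),
                           colnames(prof))
  list(counts = counts, fine_labels = fine, coarse_labels = coarse,
       profiles = prof)
}

#' Plant spatially smooth module fields on a lattice
#'
#' Generates one real-valued field per module spec over a `rows x cols`
#' lattice (spots in row-major order). `"gradient"` fields increase linearly
#' along one axis from 0 to 1; `"patch"` fields are 1 inside a disc of the
#' given radius about the given center and 0 outside. All produced fields are
#' spatially smooth (lag-1 spatial autocorrelation > 0.5 on non-degenerate
#' lattices).
#'
#' @param lattice integer vector `c(rows, cols)`.
#' @param module_specs list of module specs (see [sim_config()]).
#' @param seed integer seed (reserved for randomised field placement; the
#'   built-in field types are deterministic).
#' @return spot x module numeric matrix.
#' @export
plant_module_fields <- function(lattice, module_specs, seed = 1L) {
  rows <- as.integer(lattice[1]); cols <- as.integer(lattice[2])
  n <- rows * cols
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  out <- matrix(0, nrow = n, ncol = length(module_specs))
  for (j in seq_along(module_specs)) {
    m <- module_specs[[j]]
    if (m$field == "gradient") {
      axis <- if (is.null(m$axis)) "col" else m$axis
      v <- if (axis == "row") rr else cc
      out[, j] <- if (max(v) > 1) (v - 1) / (max(v) - 1) else 0
    } else if (m$field == "patch") {
      center <- if (is.null(m$center)) c(ceiling(rows / 2), ceiling(cols / 2)) else m$center
      radius <- if (is.null(m$radius)) max(2, floor(min(rows, cols) / 4)) else m$radius
      d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
      out[, j] <- as.numeric(d <= radius)
    } else {
      .fail("plant_module_fields", sprintf("unknown field type '%s'", m$field))
    }
  }
  colnames(out) <- sprintf("module%d", seq_along(module_specs))
  out
}

#' Moran-style lag-1 spatial autocorrelation of a lattice field
#'
#' Moran's I with rook adjacency (unit-distance lattice neighbors, equal
#' weights): `I = n/W * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`.
#'
#' @param field numeric matrix over the lattice (rows x cols).
#' @return Moran's I (scalar); `NA` for constant fields.
#' @export
lag1_autocorr <- function(field) {
  x <- field - mean(field)
  denom <- sum(x^2)
  if (denom == 0) return(NA_real_)
  nr <- nrow(field); nc <- ncol(field)
  cross <- 0; W <- 0
  if (nr > 1) {
    cross <- cross + 2 * sum(x[-nr, ] * x[-1, ])
    W <- W + 2 * (nr - 1) * nc
  }
  if (nc > 1) {
    cross <- cross + 2 * sum(x[, -nc] * x[, -1])
    W <- W + 2 * nr * (nc - 1)
  }
  (length(field) / W) * cross / denom
}

#' Simulate spot-based spatial transcriptomics tissues with ground truth
#'
#' Draws per-spot state fractions from region-specific Dirichlet laws on the
#' configured lattice, modulates component-specific expression rates by the
#' planted module fields (tumor modules act on tumor-state rates only, the
#' stromal confounder on stromal-state rates only; each modified state
#' profile is renormalised per spot), draws lognormal spot depths and
#' multinomial gene counts, and replicates the layout over `n_samples`
#' tissues x `n_slides` slides. Replicates share region geometry and module
#' fields but redraw fractions and counts independently.
#'
#' @param config a [sim_config()] object.
#' @param profiles state x gene probability matrix (rows sum to 1), e.g.
#'   `simulate_reference(config)$profiles`; default the configured truth.
#' @param seed integer seed.
#' @return list with `dataset` (a `spot_dataset`: `counts` spot x gene
#'   sparse integer matrix, `positions` data frame, `samples` data frame) and
#'   `truth` (true fractions, region labels, planted modules, module field
#'   values per spot, and a transcription-factor list containing all module
#'   genes plus background decoys).
#' @export
simulate_tissue <- function(config, profiles = NULL, seed = config$seed) {
  validate_sim_config(config)
  if (is.null(profiles)) profiles <- true_profiles(config)
  if (!is.matrix(profiles)) .fail("simulate_tissue", "profiles must be a matrix")
  .assert(ncol(profiles) == config$n_genes, "simulate_tissue",
          "profiles gene universe must match config$n_genes")
  .assert(max(abs(rowSums(profiles) - 1)) < 1e-6, "simulate_tissue",
          "profile rows must be normalized probability vectors")
  if (!identical(dim(config$region_map),
                 c(config$grid_rows, config$grid_cols))) {
    .fail("simulate_tissue", "region_map dimensions do not match the lattice")
  }
  rows <- config$grid_rows; cols <- config$grid_cols
  n_spot <- rows * cols
  K <- config$n_states
  G <- config$n_genes
  fields <- plant_module_fields(c(rows, cols), config$module_specs,
                                derive_seed(seed, 11L))
  region <- as.vector(t(config$region_map))  # row-major spot order
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)

  # per-spot state-specific rate matrices after module modulation
  mod_rates <- vector("list", K)
  for (k in seq_len(K)) {
    R <- matrix(rep(profiles[k, ], each = n_spot), nrow = n_spot)
    for (j in seq_along(config$module_specs)) {
      m <- config$module_specs[[j]]
      ids <- if (m$component == "tumor") config$tumor_state_ids else config$stromal_state_ids
      if (k %in% ids) {
        R[, m$genes] <- R[, m$genes] * (1 + m$amplitude * fields[, j])
      }
    }
    mod_rates[[k]] <- R / rowSums(R)
  }

  tissues <- expand.grid(sample_id = seq_len(config$n_samples),
                         slide_id = seq_len(config$n_slides))
  n_t <- nrow(tissues)
  all_counts <- vector("list", n_t)
  all_theta <- vector("list", n_t)
  pos_list <- vector("list", n_t)
  samp_list <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    s_id <- tissues$sample_id[t]; l_id <- tissues$slide_id[t]
    res <- with_seed(derive_seed(seed, 100L + t), {
      # Dirichlet fractions per spot from the region's concentration
      theta <- matrix(0, n_spot, K)
      for (i in seq_len(n_spot)) {
        a <- config$fraction_params[[region[i]]]
        g <- rgamma(K, shape = a, rate = 1)
        theta[i, ] <- g / sum(g)
      }
      p <- matrix(0, n_spot, G)
      for (k in seq_len(K)) p <- p + theta[, k] * mod_rates[[k]]
      depth <- pmax(50L, round(rlnorm(n_spot,
        meanlog = log(config$depth_mean) - config$depth_dispersion^2 / 2,
        sdlog = config$depth_dispersion)))
      cnt <- matrix(0L, n_spot, G)
      for (i in seq_len(n_spot)) {
        cnt[i, ] <- as.integer(rmultinom(1, depth[i], p[i, ]))
      }
      list(theta = theta, cnt = cnt)
    })
    bc <- sprintf("s%dl%d_r%02dc%02d", s_id, l_id, rr, cc)
    rownames(res$cnt) <- bc
    rownames(res$theta) <- bc
    all_counts[[t]] <- res$cnt
    all_theta[[t]] <- res$theta
    pos_list[[t]] <- data.frame(
      barcode = bc, in_tissue = 1L, array_row = rr, array_col = cc,
      pxl_row_in_fullres = rr * 100L, pxl_col_in_fullres = cc * 100L,
      stringsAsFactors = FALSE)
    samp_list[[t]] <- data.frame(barcode = bc,
                                 sample_id = sprintf("mouse%d", s_id),
                                 slide_id = sprintf("slide%d", l_id),
                                 stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, all_counts)
  colnames(counts) <- colnames(profiles)
  theta <- do.call(rbind, all_theta)
  colnames(theta) <- rownames(profiles)
  positions <- do.call(rbind, pos_list)
  samples <- do.call(rbind, samp_list)

  gn <- colnames(profiles)
  planted <- lapply(config$module_specs, function(m) {
    list(component = m$component, genes = gn[m$genes])
  })
  module_genes <- unique(unlist(lapply(planted, `[[`, "genes")))
  n_mark <- config$n_states * config$markers_per_state
  max_module <- max(unlist(lapply(config$module_specs, `[[`, "genes")))
  decoys <- if (max_module < G) {
    gn[setdiff(seq(max_module + 1L, G), seq_len(n_mark))]
  } else character(0)
  decoys <- decoys[seq_len(min(30L, length(decoys)))]
  tf_list <- c(module_genes, decoys)

  dataset <- structure(list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    positions = positions, samples = samples), class = "spot_dataset")
  amp <- vapply(config$module_specs, `[[`, numeric(1), "amplitude")
  eff_fields <- sweep(fields, 2, amp, `*`)   # the multiplicative effect size
  truth <- list(true_fractions = theta,
                region_label = setNames(rep(region, n_t), rownames(counts)),
                planted_modules = planted,
                module_field_values = eff_fields[rep(seq_len(n_spot), n_t), ,
                                                 drop = FALSE],
                tf_list = tf_list)
  rownames(truth$module_field_values) <- rownames(counts)
  list(dataset = dataset, truth = truth)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes, %d tissue(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(paste(x$samples$sample_id, x$samples$slide_id)))))
  invisible(x)
}
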