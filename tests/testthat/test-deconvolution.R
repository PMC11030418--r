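make_ref <- function(phi, pseudo_min = 0) {
  dimnames(phi) <- list(sprintf("S%d", seq_len(nrow(phi))),
                        sprintf("g%d", seq_len(ncol(phi))))
  structure(list(profile = phi, fine_labels = rownames(phi),
                 coarse_labels = NULL, marker_genes = NULL,
                 pseudo_min = pseudo_min), class = "reference_profile")
}

spot_ds_from_counts <- function(cnt) {
  colnames(cnt) <- sprintf("g%d", seq_len(ncol(cnt)))
  toy_spot_dataset(cnt, rows = nrow(cnt), cols = 1L)
}

test_that("spot and gene filters apply the quoted strict boundaries", {
  # genes: expressed in 3 spots -> removed; in 4 spots -> retained
  cnt <- matrix(0L, 6, 3)
  cnt[1:3, 1] <- 1200L
  cnt[1:4, 2] <- 1200L
  cnt[, 3] <- 500L
  ds <- spot_ds_from_counts(cnt)
  out <- filter_spots_and_genes(ds, min_spot_genes = 1, min_spot_umis = 1,
                                min_gene_spots_exclusive = 3)
  expect_setequal(colnames(out$counts), c("g2", "g3"))
  # spots: exactly 1000 genes and 1000 UMIs retained
  cnt2 <- matrix(0L, 3, 1200)
  cnt2[1, 1:1000] <- 1L          # 1000 genes, 1000 UMIs -> retained
  cnt2[2, 1:999] <- 2L           # 999 genes -> removed
  cnt2[3, 1:1200] <- 1L          # retained
  ds2 <- toy_spot_dataset(cnt2, rows = 3, cols = 1)
  out2 <- filter_spots_and_genes(ds2, min_gene_spots_exclusive = 0)
  expect_equal(nrow(out2$counts), 2L)
  expect_error(filter_spots_and_genes(ds2, min_spot_genes = 1e6),
               "no spots")
})

test_that("EM reproduces closed-form mixture weights", {
  phi <- rbind(c(1, 0), c(0, 1))
  ref <- make_ref(phi)
  ds <- spot_ds_from_counts(rbind(c(3L, 1L)))
  dec <- suppressWarnings(deconvolve(ds, ref))
  expect_equal(unname(dec$theta[1, ]), c(0.75, 0.25), tolerance = 1e-6)
  # disjoint support: counts only on state-A genes
  ds2 <- spot_ds_from_counts(rbind(c(7L, 0L)))
  dec2 <- suppressWarnings(deconvolve(ds2, ref))
  expect_equal(unname(dec2$theta[1, 1]), 1, tolerance = 1e-6)
  expect_equal(sum(dec2$z[[2]]), 0, tolerance = 1e-9)
  expect_equal(sum(dec2$z[[1]]), 7)
})

test_that("EM matches a brute-force grid search on random instances", {
  set.seed(31)
  grid_mle <- function(cnt, phi, step = 0.001) {
    best <- NULL; best_ll <- -Inf
    for (t1 in seq(0, 1, step)) {
      t2 <- seq(0, 1 - t1, step)
      t3 <- 1 - t1 - t2
      p <- cbind(t1 * phi[1, 1] + t2 * phi[2, 1] + t3 * phi[3, 1],
                 t1 * phi[1, 2] + t2 * phi[2, 2] + t3 * phi[3, 2])
      # vectorised over t2 for all genes
      P <- outer(t2, rep(1, ncol(phi))) * 0
      for (g in seq_len(ncol(phi))) {
        P[, g] <- t1 * phi[1, g] + t2 * phi[2, g] + t3 * phi[3, g]
      }
      ll <- as.vector(log(pmax(P, 1e-300)) %*% cnt)
      i <- which.max(ll)
      if (ll[i] > best_ll) { best_ll <- ll[i]; best <- c(t1, t2[i], t3[i]) }
    }
    best
  }
  for (rep in 1:5) {
    phi <- matrix(rgamma(30, 1), 3, 10)
    phi <- phi / rowSums(phi)
    cnt <- as.integer(rmultinom(1, 300, colMeans(phi)))
    ref <- make_ref(phi)
    ds <- spot_ds_from_counts(matrix(cnt, 1))
    dec <- deconvolve(ds, ref, tol = 1e-12, max_iter = 5000)
    oracle <- grid_mle(cnt, phi)
    expect_lt(max(abs(dec$theta[1, ] - oracle)), 0.005)
  }
})

test_that("responsibility allocation conserves counts and EM is monotone", {
  pr <- default_prepped(1)
  dec <- pr$dec
  recon <- Reduce(`+`, dec$z)
  obs <- as.matrix(dec$spots$counts)
  expect_lt(max(abs(as.matrix(recon) - obs)), 1e-6 * max(1, max(obs)))
  # monotone log-likelihood trace on a small re-run
  cfg <- small_config(seed = 2)
  tis <- simulate_tissue(cfg, seed = 2)
  prof <- simulate_reference(cfg, seed = 2)$profiles
  ref <- make_ref(prof)
  colnames(ref$profile) <- colnames(tis$dataset$counts)
  dec2 <- suppressWarnings(
    deconvolve(tis$dataset, ref, keep_trace = TRUE))
  for (tr in dec2$loglik_trace[1:20]) {
    if (length(tr) > 1) expect_true(all(diff(tr) >= -1e-7 * abs(tr[-1])))
  }
})

test_that("theta columns permute with the reference states", {
  cfg <- small_config(seed = 3)
  tis <- simulate_tissue(cfg, seed = 3)
  prof <- simulate_reference(cfg, seed = 3)$profiles
  r1 <- make_ref(prof)
  colnames(r1$profile) <- colnames(tis$dataset$counts)
  perm <- c(3, 1, 2)
  r2 <- r1
  r2$profile <- r1$profile[perm, ]
  d1 <- suppressWarnings(deconvolve(tis$dataset, r1))
  d2 <- suppressWarnings(deconvolve(tis$dataset, r2))
  expect_equal(unname(d1$theta[, perm]), unname(d2$theta),
               tolerance = 1e-8)
})

test_that("tumor counts are the ceiling of summed tumor allocations", {
  z1 <- Matrix::Matrix(matrix(c(1.3, 0, 2, 0.2), 2, 2), sparse = TRUE)
  z2 <- Matrix::Matrix(matrix(c(1.0, 0, 0.5, 0), 2, 2), sparse = TRUE)
  fake <- structure(list(z = list(A = z1, B = z2), states = c("A", "B")),
                    class = "spot_deconv")
  out <- tumor_counts(fake, c("A", "B"))
  expect_identical(out[1, 1], 3L)   # 2.3 -> 3
  expect_identical(out[2, 1], 0L)   # 0 -> 0
  expect_identical(out[1, 2], 3L)   # 2.5 -> 3
  expect_error(tumor_counts(fake, character(0)), "non-empty")
  expect_error(tumor_counts(fake, "C"), "unknown state")
})

test_that("pure-tumor spots conserve totals through tumor_counts", {
  cfg <- small_config(seed = 4)
  cfg$fraction_params <- list(NE = c(1e6, 1e-6, 1e-6))  # all tumor state 1
  tis <- simulate_tissue(cfg, seed = 4)
  prof <- simulate_reference(cfg, seed = 4)$profiles
  ref <- make_ref(prof)
  colnames(ref$profile) <- colnames(tis$dataset$counts)
  dec <- suppressWarnings(deconvolve(tis$dataset, ref))
  tum <- tumor_counts(dec, 1:3)   # all states: ceiling(z sums) = counts
  expect_equal(unname(rowSums(tum)),
               unname(Matrix::rowSums(tis$dataset$counts)))
})

test_that("fraction maps respect the simplex and recover planted geometry", {
  pr <- default_prepped(1)
  all_states <- celltype_fraction_map(pr$dec, pr$dec$states)
  expect_equal(unname(all_states), rep(1, nrow(pr$dec$theta)),
               tolerance = 1e-8)
  none <- celltype_fraction_map(pr$dec, character(0))
  expect_true(all(none == 0))
  ne <- celltype_fraction_map(pr$dec, pr$dec$states[1])
  region <- pr$tis$truth$region_label[names(ne)]
  expect_gt(mean(ne[region == "NE"]), mean(ne[region == "nonNE"]))
})

test_that("replicate concordance behaves on a fixed 5-region toy", {
  mk_dec <- function(theta) {
    rownames(theta) <- sprintf("b%d", seq_len(nrow(theta)))
    colnames(theta) <- c("S1", "S2", "S3")
    structure(list(theta = theta, states = c("S1", "S2", "S3")),
              class = "spot_deconv")
  }
  set.seed(11)
  th <- matrix(rgamma(15 * 3, 2), 15, 3)
  th <- th / rowSums(th)
  regions <- setNames(rep(sprintf("R%d", 1:5), each = 3),
                      sprintf("b%d", 1:15))
  dA <- mk_dec(th)
  cc <- replicate_concordance(dA, dA, regions, regions)
  expect_equal(unname(cc$r_celltype), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(cc$r_region), rep(1, 5), tolerance = 1e-12)
  # permuting regions degrades correlation
  perm_regions <- setNames(regions[c(13:15, 1:12)], names(regions))
  cc2 <- replicate_concordance(dA, dA, regions, perm_regions)
  expect_lt(mean(cc2$r_celltype), 1)
  expect_error(replicate_concordance(dA, dA, regions[regions == "R1"],
                                     regions[regions == "R1"]),
               ">= 2")
})

test_that("Pearson correlation matches the closed-form oracle", {
  x <- c(0.1, 0.2, 0.7); y <- c(0.2, 0.1, 0.7)
  # closed form: sum(dx dy) / sqrt(sum dx^2 sum dy^2) = 177/186
  dx <- x - mean(x); dy <- y - mean(y)
  oracle <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(oracle, 177 / 186, tolerance = 1e-12)
  expect_equal(cor(x, y), oracle, tolerance = 1e-12)
})

test_that("a positive count on a zero-probability gene is floored with warning", {
  phi <- rbind(c(1, 0), c(0.5, 0.5))
  ref <- make_ref(phi)
  ds <- spot_ds_from_counts(rbind(c(1L, 5L)))
  expect_warning(deconvolve(ds, ref), "zero reference probability")
})
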