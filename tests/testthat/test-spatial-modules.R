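grid_positions <- function(rows, cols, shift_row = 0, shift_col = 0,
                           prefix = "a") {
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  data.frame(barcode = sprintf("%s_r%dc%d", prefix, rr, cc),
             array_row = rr + shift_row, array_col = cc + shift_col)
}

test_that("kNN graph on a regular grid picks adjacent spots, no cross-tissue edges", {
  pos <- grid_positions(7, 7)
  g <- build_knn_graph(pos, rep("t1", 49), k = 6)
  center <- which(pos$array_row == 4 & pos$array_col == 4)
  nb <- g$nn[center, ]
  d <- sqrt((pos$array_row[nb] - 4)^2 + (pos$array_col[nb] - 4)^2)
  expect_true(all(d <= sqrt(2) + 1e-12))   # 4 rook + 2 diagonal neighbors
  expect_false(center %in% nb)             # self stored separately
  expect_equal(Matrix::diag(g$adj), rep(1, 49))  # self included in adjacency

  # two tissues: zero cross-tissue edges whatever the coordinates
  pos2 <- rbind(grid_positions(5, 5, prefix = "a"),
                grid_positions(5, 5, prefix = "b"))
  tiss <- rep(c("A", "B"), each = 25)
  g2 <- build_knn_graph(pos2, tiss, k = 4)
  for (i in 1:50) expect_true(all(tiss[g2$nn[i, ]] == tiss[i]))
  expect_error(build_knn_graph(grid_positions(2, 2), rep("t", 4), k = 6),
               "<= k spots")
})

test_that("coordinate shifting and tissue partitioning build identical graphs", {
  posA <- grid_positions(5, 6, prefix = "a")
  posB <- grid_positions(5, 6, prefix = "b")
  tiss <- rep(c("A", "B"), each = 30)
  g_part <- build_knn_graph(rbind(posA, posB), tiss, k = 6)
  posB_shift <- posB
  posB_shift$array_row <- posB_shift$array_row + 1000
  posB_shift$array_col <- posB_shift$array_col + 1000
  g_shift <- build_knn_graph(rbind(posA, posB_shift), rep("one", 60), k = 6)
  edges <- function(g) {
    sort(paste(rep(seq_len(nrow(g$nn)), ncol(g$nn)), as.vector(g$nn)))
  }
  expect_identical(edges(g_part), edges(g_shift))
})

test_that("residuals are centred, standardised and equivariant", {
  d <- c(100, 200, 300, 400)
  p <- c(0.25, 0.75)
  cnt <- outer(d, p)   # exactly depth-proportional
  dimnames(cnt) <- list(sprintf("s%d", 1:4), c("g1", "g2"))
  r <- standardized_residuals(cnt, d)
  expect_true(all(abs(r) < 1e-12))
  # Poisson-simulated genes have residual variance near 1
  set.seed(5)
  n <- 1000
  depth <- rep(2000, n)
  pg <- c(0.002, 0.01, 0.05)
  cnt2 <- vapply(pg, function(p) rpois(n, depth * p), numeric(n))
  colnames(cnt2) <- sprintf("g%d", 1:3)
  r2 <- standardized_residuals(cnt2, depth)
  v <- apply(r2, 2, var)
  expect_true(all(v > 0.8 & v < 1.2))
  # permuting spots permutes residual rows identically
  perm <- sample(n)
  r_perm <- standardized_residuals(cnt2[perm, ], depth[perm])
  expect_equal(r_perm, r2[perm, ], tolerance = 1e-12)
  expect_error(standardized_residuals(cbind(cnt2, g0 = 0), depth),
               "zero total")
})

test_that("autocorrelation flags planted spatial signal and not noise", {
  set.seed(21)
  pos <- grid_positions(20, 20)
  g <- build_knn_graph(pos, rep("t", 400), k = 6)
  grad <- (pos$array_col - 1) / 19
  X <- cbind(signal = scale(grad + rnorm(400, 0, 0.5))[, 1],
             noise = rnorm(400),
             flat = rep(0, 400))
  ac <- autocorrelation(X, g, n_perm = 300, seed = 2)
  expect_gt(ac$Z[ac$gene == "signal"], 5)
  expect_lt(ac$fdr[ac$gene == "signal"], 0.01)
  expect_lt(abs(ac$Z[ac$gene == "noise"]), 4)
  expect_equal(ac$Z[ac$gene == "flat"], 0)   # degenerate null sd guarded
  expect_equal(ac$H[ac$gene == "flat"], 0)
  expect_warning(autocorrelation(X, g, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on a 5-spot toy", {
  pos <- data.frame(barcode = sprintf("s%d", 1:5),
                    array_row = c(1, 1, 2, 2, 3),
                    array_col = c(1, 2, 1, 2, 1))
  g <- build_knn_graph(pos, rep("t", 5), k = 2)
  x <- matrix(c(1.2, -0.7, 0.5, -1.4, 0.9), ncol = 1,
              dimnames = list(pos$barcode, "g"))
  stat <- function(v) sum(v * as.vector(g$adj %*% v)) / 3
  perms <- NULL  # exhaustive: all 120 permutations of 5 spots
  idx <- 1:5
  allperm <- as.matrix(expand.grid(rep(list(idx), 5)))
  allperm <- allperm[apply(allperm, 1, function(r) length(unique(r)) == 5), ]
  h_null <- apply(allperm, 1, function(pr) stat(x[pr, 1]))
  h_obs <- stat(x[, 1])
  p_exact <- mean(h_null >= h_obs)
  ac <- autocorrelation(x, g, n_perm = 2000, seed = 3,
                        min_tissue_spots = 0)
  expect_equal(ac$H, h_obs, tolerance = 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(ac$p - p_exact), 4 * se + 1 / 2000)
})

test_that("the local-correlation diagonal equals the autocorrelation statistic", {
  set.seed(9)
  pos <- grid_positions(10, 10)
  g <- build_knn_graph(pos, rep("t", 100), k = 6)
  X <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(pos$barcode, sprintf("g%d", 1:8)))
  ac <- autocorrelation(X, g, n_perm = 100, seed = 1)
  lc <- local_correlation(X, g, colnames(X), n_perm = 100, seed = 1)
  expect_equal(unname(diag(lc$C)), ac$H, tolerance = 1e-12)
  expect_equal(lc$Z, t(lc$Z))
  expect_equal(lc$C, t(lc$C), tolerance = 1e-12)
})

test_that("duplicated planted signal yields matching pairwise and self Z", {
  set.seed(13)
  pos <- grid_positions(15, 15)
  g <- build_knn_graph(pos, rep("t", 225), k = 6)
  sig <- scale((pos$array_col - 1) / 14 + rnorm(225, 0, 0.4))[, 1]
  X <- cbind(a = sig, b = sig, c = rnorm(225))
  rownames(X) <- pos$barcode
  lc <- local_correlation(X, g, c("a", "b", "c"), n_perm = 300, seed = 2)
  expect_equal(lc$C["a", "b"], lc$C["a", "a"], tolerance = 1e-12)
  expect_gt(lc$Z["a", "b"], 5)
  expect_equal(lc$Z["a", "b"] / lc$Z["a", "a"], 1, tolerance = 0.35)
})

test_that("white-noise gene pairs rarely reach |Z| = 3", {
  set.seed(17)
  pos <- grid_positions(12, 12)
  g <- build_knn_graph(pos, rep("t", 144), k = 6)
  X <- matrix(rnorm(144 * 15), 144, 15,
              dimnames = list(pos$barcode, sprintf("g%d", 1:15)))
  lc <- local_correlation(X, g, colnames(X), n_perm = 300, seed = 4)
  off <- lc$Z[upper.tri(lc$Z)]   # 105 independent pairs
  expect_gte(mean(abs(off) < 3), 0.95)
})

test_that("module gene selection applies FDR, TF and rank rules strictly", {
  ac <- data.frame(gene = sprintf("g%03d", 1:700),
                   H = 0, Z = seq(700, 1, -1),
                   p = 0.001, fdr = 0.001)
  ac$fdr[1] <- 0.01           # exactly at the threshold -> excluded
  tf <- sprintf("g%03d", 1:650)
  sel <- select_module_genes(ac, tf, fdr_max = 0.01, top_n = 500)
  expect_length(sel, 500)
  expect_false("g001" %in% sel)            # FDR == 0.01 excluded
  expect_false(any(sprintf("g%03d", 651:700) %in% sel))  # non-TF excluded
  expect_identical(sel[1], "g002")         # top Z among eligible
  expect_warning(sel0 <- select_module_genes(ac, character(0)),
                 "no significant")
  expect_length(sel0, 0)
})

test_that("block-diagonal Z recovers planted modules and dissolves small ones", {
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  Z <- matrix(0, n, n, dimnames = list(genes, genes))
  P <- matrix(0.5, n, n, dimnames = list(genes, genes))
  blocks <- split(1:n, rep(1:3, each = 20))
  for (b in blocks) {
    Z[b, b] <- 10
    P[b, b] <- 1e-4
  }
  diag(Z) <- 0
  lc <- structure(list(C = Z, Z = Z, p = P, genes = genes, n_perm = 1000L),
                  class = "local_corr")
  mod <- detect_modules(lc, min_gene_threshold = 15, fdr_threshold = 0.05)
  expect_length(mod$modules, 3)
  # oracle: connected components of the thresholded Z coincide here
  for (b in blocks) {
    ids <- unique(mod$assignment[genes[b]])
    expect_length(ids, 1)
    expect_true(ids != -1)
  }
  # distinct blocks in distinct modules
  expect_length(unique(mod$assignment), 3)

  # a significant block of 10 (< 15) dissolves under core_only
  Z2 <- matrix(0, 12, 12); P2 <- matrix(0.5, 12, 12)
  Z2[1:10, 1:10] <- 8; P2[1:10, 1:10] <- 1e-4; diag(Z2) <- 0
  g2 <- sprintf("h%02d", 1:12)
  dimnames(Z2) <- dimnames(P2) <- list(g2, g2)
  lc2 <- structure(list(C = Z2, Z = Z2, p = P2, genes = g2,
                        n_perm = 1000L), class = "local_corr")
  mod2 <- detect_modules(lc2, min_gene_threshold = 15)
  expect_true(all(mod2$assignment == -1))
  mod2b <- detect_modules(lc2, min_gene_threshold = 10)
  expect_equal(sum(mod2b$assignment != -1), 10)
  # genes with no significant pair stay unassigned
  expect_equal(unname(mod2b$assignment["h11"]), -1L)
})

test_that("module scores smooth the z-scored expression over the graph", {
  set.seed(3)
  pos <- grid_positions(6, 6)
  g <- build_knn_graph(pos, rep("t", 36), k = 4)
  prof <- rnorm(36)
  X <- cbind(g1 = prof, g2 = prof, g3 = rep(2, 36))
  rownames(X) <- pos$barcode
  sc <- module_scores(X, list(m1 = c("g1", "g2"), m2 = "g3"), g)
  zprof <- (prof - mean(prof)) / sd(prof)
  expected <- as.vector(g$adj %*% zprof) / 5
  expect_equal(unname(sc[, "m1"]), expected, tolerance = 1e-12)
  expect_equal(unname(sc[, "m2"]), rep(0, 36))  # constant gene -> 0 score
})
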