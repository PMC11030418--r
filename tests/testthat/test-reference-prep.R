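make_cells <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  m
}

test_that("cell QC thresholds are read strictly at their boundaries", {
  # 250 genes so detection counts can straddle the 200-gene threshold
  base <- matrix(0L, 4, 250, dimnames = list(sprintf("c%d", 1:4),
                                             sprintf("g%d", 1:250)))
  base[1, 1:199] <- 6L   # 199 detected genes, 1194 UMIs -> removed
  base[2, 1:200] <- 5L   # 200 genes, 1000 UMIs exactly -> retained
  base[3, 1:250] <- 4L   # 1000 UMIs, 250 genes, no mito -> retained
  base[4, 1:240] <- 5L; base[4, 250] <- 120L  # mito frac 0.0909 <= 0.10
  colnames(base)[250] <- "mt-1"
  kept <- filter_reference_cells(base, mito_genes = "mt-1")
  expect_setequal(rownames(kept), c("c2", "c3", "c4"))
  # mito fraction exactly 0.10 is retained ("above 10%" removes only > 0.10)
  m <- base[4, , drop = FALSE]
  m[1, "mt-1"] <- 0L
  m[1, 1:225] <- 4L
  m[1, "mt-1"] <- 100L   # total 1000, mito 0.10
  expect_equal(nrow(filter_reference_cells(m, mito_genes = "mt-1")), 1L)
  expect_error(filter_reference_cells(base * 0L), "no cells pass")
})

test_that("gene filter keeps >= 3 detecting cells and honours drop sets", {
  m <- make_cells(c(1, 1, 0, 5), c(1, 0, 0, 5), c(1, 0, 0, 5),
                  c(0, 0, 0, 5))
  out <- filter_reference_genes(m, min_cells = 3)
  expect_setequal(colnames(out), c("g1", "g4"))  # g1 detected in exactly 3
  out2 <- filter_reference_genes(m, min_cells = 3,
                                 drop_sets = list(ribo = "g4"))
  expect_setequal(colnames(out2), "g1")
  expect_true(!"g3" %in% colnames(out))          # all-zero gene removed
})

test_that("filters are idempotent", {
  cfg <- small_config(seed = 8)
  ref <- simulate_reference(cfg, seed = 8)
  f1 <- filter_reference_cells(ref$counts, min_genes = 20, min_umis = 400)
  expect_identical(filter_reference_cells(f1, min_genes = 20,
                                          min_umis = 400), f1)
  g1 <- filter_reference_genes(f1, min_cells = 3)
  expect_identical(filter_reference_genes(g1, min_cells = 3), g1)
})

test_that("log2 cp10k normalisation matches its closed form", {
  m <- matrix(c(10, 9990, 0, 10000), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  n <- normalize_log2_cp10k(m)
  expect_equal(n["a", "g1"], log2(11))
  expect_equal(n["b", "g1"], 0)
  expect_equal(normalize_log2_cp10k(2 * m), n)  # per-cell scale invariance
  m0 <- rbind(m, c(0, 0))
  expect_error(normalize_log2_cp10k(m0), "zero total")
})

test_that("marker selection agrees with direct Welch t-tests and recovers planted markers", {
  cfg <- small_config(seed = 6, marker_fold = 10, n_cells = 100)
  ref <- simulate_reference(cfg, seed = 6)
  norm <- normalize_log2_cp10k(ref$counts)
  coarse <- tapply(ref$coarse_labels, ref$fine_labels, function(x) x[1])
  mk <- select_markers(norm, ref$fine_labels, coarse)
  states <- sort(unique(ref$fine_labels))
  # planted exclusive markers recovered for their own state only
  for (k in 1:3) {
    planted <- sprintf("g%04d", (k - 1) * 5 + 1:5)
    expect_true(all(planted %in% mk$markers[[states[k]]]))
    for (j in setdiff(1:3, k)) {
      expect_false(any(planted %in% mk$markers[[states[j]]]))
    }
  }
  # independent oracle: stats::t.test + lfc for a few genes of state 1
  s1 <- states[1]
  lin <- 2^norm - 1
  for (g in c("g0001", "g0030", "g0055")) {
    ps <- lfcs <- numeric(0)
    for (o in states[-1]) {
      a <- norm[ref$fine_labels == s1, g]
      b <- norm[ref$fine_labels == o, g]
      ps <- c(ps, t.test(a, b)$p.value)
      lfcs <- c(lfcs, log2((mean(lin[ref$fine_labels == s1, g]) + 1) /
                             (mean(lin[ref$fine_labels == o, g]) + 1)))
    }
    row <- mk$stats[mk$stats$gene == g & mk$stats$state == s1, ]
    expect_equal(row$max_p, max(ps), tolerance = 1e-8)
    expect_equal(row$min_lfc, min(lfcs), tolerance = 1e-8)
  }
})

test_that("the marker AND-rule and tumor-vs-tumor skipping follow the stated rules", {
  # two tumor states sharing a high gene, two non-tumor states
  set.seed(42)
  n <- 30
  labels <- rep(c("T1", "T2", "N1", "N2"), each = n)
  coarse <- c(T1 = "tumor", T2 = "tumor", N1 = "other", N2 = "other")
  G <- 6
  counts <- matrix(rpois(4 * n * G, 20), ncol = G,
                   dimnames = list(NULL, sprintf("g%d", 1:G)))
  counts[labels %in% c("T1", "T2"), 1] <- rpois(2 * n, 200)  # shared tumor gene
  counts[labels == "T1", 2] <- rpois(n, 200)                 # T1 only
  norm <- normalize_log2_cp10k(counts)
  mk <- select_markers(norm, labels, coarse)
  expect_true("g1" %in% mk$markers$T1)
  expect_true("g1" %in% mk$markers$T2)   # tumor-vs-tumor pair skipped
  expect_true("g2" %in% mk$markers$T1)
  expect_false("g2" %in% mk$markers$N1)
})

test_that("a small fold change is excluded however significant (AND rule)", {
  set.seed(7)
  n <- 200
  labels <- rep(c("A", "B"), each = n)
  # gene 1: lfc ~ 0.05 on the linear scale but tiny variance -> p ~ 0
  norm <- cbind(g1 = c(rnorm(n, 1.07, 0.01), rnorm(n, 1.00, 0.01)),
                g2 = c(rnorm(n, 3.00, 0.10), rnorm(n, 1.00, 0.10)))
  mk <- select_markers(norm, labels, c(A = "other", B = "other"))
  st <- mk$stats[mk$stats$gene == "g1" & mk$stats$state == "A", ]
  expect_lt(st$max_p, 0.01)
  expect_lt(st$min_lfc, 0.1)
  expect_false("g1" %in% mk$markers$A)
  expect_true("g2" %in% mk$markers$A)
})

test_that("marker selection is equivariant under state relabeling", {
  cfg <- small_config(seed = 9, n_cells = 50)
  ref <- simulate_reference(cfg, seed = 9)
  norm <- normalize_log2_cp10k(ref$counts)
  coarse <- tapply(ref$coarse_labels, ref$fine_labels, function(x) x[1])
  mk1 <- select_markers(norm, ref$fine_labels, coarse)
  relabel <- setNames(paste0("X_", sort(unique(ref$fine_labels))),
                      sort(unique(ref$fine_labels)))
  fine2 <- unname(relabel[ref$fine_labels])
  coarse2 <- setNames(coarse, relabel[names(coarse)])
  mk2 <- select_markers(norm, fine2, coarse2)
  for (s in names(mk1$markers)) {
    expect_setequal(mk1$markers[[s]], mk2$markers[[relabel[s]]])
  }
})

test_that("a signal-free reference yields almost no markers", {
  hits <- total <- 0
  for (s in 1:10) {
    cfg <- small_config(seed = s, marker_fold = 1, n_cells = 40)
    cfg$module_specs[[1]]$amplitude <- 0
    ref <- simulate_reference(cfg, seed = s + 100)
    norm <- normalize_log2_cp10k(ref$counts)
    coarse <- tapply(ref$coarse_labels, ref$fine_labels, function(x) x[1])
    mk <- select_markers(norm, ref$fine_labels, coarse)
    hits <- hits + length(unique(unlist(mk$markers)))
    total <- total + cfg$n_genes
  }
  expect_lt(hits / total, 0.01)
})

test_that("reference profiles are state means floored and normalised", {
  m <- make_cells(c(2, 0, 8), c(4, 0, 8), c(1, 1, 1))
  prof <- build_reference(m, c("A", "A", "B"), pseudo_min = 0)
  # state A, gene 1: mean of (2, 4) = 3 before normalisation
  expect_equal(prof$profile["A", "g1"] / prof$profile["A", "g3"], 3 / 8)
  expect_equal(prof$profile["A", "g2"], 0)    # pseudo_min = 0, no pseudocount
  expect_equal(unname(rowSums(prof$profile)), c(1, 1))
  expect_error(build_reference(m, c("A", "A", "B"), universe = c("g2")),
               "zero total")
})

test_that("marker_fold = 1 leaves markers statistically indistinguishable", {
  cfg <- small_config(seed = 12, marker_fold = 1, n_cells = 100)
  ref <- simulate_reference(cfg, seed = 12)
  means <- rowsum(ref$counts, ref$fine_labels) /
    as.vector(table(ref$fine_labels))
  g <- 1:5  # nominal markers of state 1
  expect_lt(max(means[1, g] / pmax(means[2, g], 0.01)), 2)
})
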