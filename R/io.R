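# Readers and writers for the 10x MatrixMarket triplet, Visium-style
# positions tables, per-spot sample assignments and gene lists.

#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads `matrix.mtx` (MatrixMarket coordinate format, genes x barcodes, as
#' 10x writes it), `features.tsv` (gene id and symbol) and `barcodes.tsv`
#' from a directory and returns counts oriented barcode x gene.
#'
#' @param dir directory containing the triplet.
#' @return list with `counts` (sparse barcode x gene integer matrix),
#'   `features` (data frame), `barcodes` (character).
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (p in paths) {
    if (!file.exists(p)) .fail("read_counts_mtx", sprintf("missing file %s", p))
  }
  m <- tryCatch(Matrix::readMM(paths[1]), error = function(e) {
    .fail("read_counts_mtx",
          sprintf("malformed MatrixMarket file %s: %s", paths[1],
                  conditionMessage(e)))
  })
  hdr <- readLines(paths[1], n = 50L)
  hdr <- hdr[!startsWith(hdr, "%")][1]
  nnz_declared <- as.integer(strsplit(trimws(hdr), "\\s+")[[1]][3])
  if (!is.na(nnz_declared) && nnz_declared != length(m@x)) {
    .fail("read_counts_mtx",
          sprintf("truncated %s: header declares %d entries, found %d",
                  paths[1], nnz_declared, length(m@x)))
  }
  if (any(m@x %% 1 != 0)) {
    bad <- which(m@x %% 1 != 0)[1]
    .fail("read_counts_mtx",
          sprintf("non-integer entry (value %g, stored entry %d) in %s",
                  m@x[bad], bad, paths[1]))
  }
  features <- read.table(paths[2], sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  colnames(features)[1:2] <- c("gene_id", "symbol")[seq_len(min(2, ncol(features)))]
  barcodes <- read.table(paths[3], sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[, 1]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m)) {
    .fail("read_counts_mtx", sprintf(
      "header/data mismatch in %s: matrix is %d x %d but %d features / %d barcodes",
      dir, nrow(m), ncol(m), nrow(features), length(barcodes)))
  }
  counts <- Matrix::t(m)
  symbols <- if ("symbol" %in% colnames(features)) features$symbol
             else features[, 1]
  dimnames(counts) <- list(barcodes, symbols)
  list(counts = counts, features = features, barcodes = barcodes)
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' @param counts barcode x gene count matrix (written transposed, genes x
#'   barcodes, as 10x does).
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(Matrix::t(counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  genes <- colnames(counts)
  write.table(data.frame(gene_id = genes, symbol = genes),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(rownames(counts)), file.path(dir, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(dir)
}

#' Read a Visium-style positions table
#'
#' Accepts both the headered dialect
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`)
#' and the legacy headerless 6-column dialect.
#'
#' @param path CSV path.
#' @param barcodes optional barcodes that must all be present.
#' @return data frame with the six standard columns; duplicate barcodes are
#'   an error; out-of-tissue spots carry `in_tissue == 0`.
#' @export
read_positions <- function(path, barcodes = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  pos <- read.table(path, sep = ",", header = has_header,
                    stringsAsFactors = FALSE)
  .assert(ncol(pos) == 6, "read_positions",
          sprintf("expected 6 columns in %s, found %d", path, ncol(pos)))
  colnames(pos) <- cols
  if (anyDuplicated(pos$barcode)) {
    .fail("read_positions", sprintf("duplicate barcode(s) in %s: %s", path,
          paste(head(unique(pos$barcode[duplicated(pos$barcode)]), 5),
                collapse = ", ")))
  }
  if (!is.null(barcodes)) {
    missing <- setdiff(barcodes, pos$barcode)
    if (length(missing)) {
      .fail("read_positions",
            sprintf("%d barcode(s) in counts but absent from positions: %s",
                    length(missing), paste(head(missing, 5), collapse = ", ")))
    }
  }
  pos
}

#' Read a per-spot sample/slide assignment table
#'
#' Tab-separated with columns `barcode`, `sample_id`, `slide_id` (header
#' optional).
#'
#' @param path TSV path.
#' @return data frame with those three columns.
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  s <- read.table(path, sep = "\t", header = has_header,
                  stringsAsFactors = FALSE)
  .assert(ncol(s) >= 3, "read_samples", "need barcode, sample_id, slide_id")
  colnames(s)[1:3] <- c("barcode", "sample_id", "slide_id")
  s
}

#' Read a gene list (one symbol per line)
#' @param path text file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Assemble a `spot_dataset` from its on-disk parts
#'
#' @param counts_dir 10x MTX triplet directory.
#' @param positions_path Visium-style positions CSV.
#' @param samples_path samples TSV (barcode, sample_id, slide_id).
#' @param drop_out_of_tissue exclude spots with `in_tissue == 0`.
#' @return a `spot_dataset`.
#' @export
read_spot_dataset <- function(counts_dir, positions_path, samples_path,
                              drop_out_of_tissue = TRUE) {
  cm <- read_counts_mtx(counts_dir)
  pos <- read_positions(positions_path, barcodes = rownames(cm$counts))
  smp <- read_samples(samples_path)
  ds <- structure(list(counts = cm$counts,
                       positions = pos[match(rownames(cm$counts), pos$barcode), ],
                       samples = smp[match(rownames(cm$counts), smp$barcode), ]),
                  class = "spot_dataset")
  if (drop_out_of_tissue) {
    keep <- which(ds$positions$in_tissue == 1)
    ds <- subset_spot_dataset(ds, keep)
  }
  ds
}

#' Write a `spot_dataset` to disk (MTX triplet + positions CSV + samples TSV)
#' @param dataset a `spot_dataset`.
#' @param dir output directory.
#' @export
write_spot_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(dataset$counts, dir)
  write.table(dataset$positions, file.path(dir, "positions.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(dataset$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
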