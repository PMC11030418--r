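#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix readMM writeMM sparseMatrix t colSums rowSums crossprod
#' @importFrom stats pt p.adjust rmultinom rlnorm sd cor var rnorm runif
#'   t.test wilcox.test setNames rgamma
#' @importFrom utils read.table write.table head
NULL

# stop() wrapper adding the calling stage name to pipeline errors
.fail <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

.assert <- function(ok, stage, msg) {
  if (!isTRUE(ok)) .fail(stage, msg)
}

# derive a child seed from a master seed; kept below 2^31
derive_seed <- function(master_seed, index) {
  (as.integer(master_seed) + 10007L * as.integer(index)) %% 2147483647L
}

# dense-or-sparse safe accessors
.as_matrix <- function(x) as.matrix(x)

# per-tissue index list from sample/slide ids
tissue_split <- function(sample_id, slide_id) {
  split(seq_along(sample_id), paste(sample_id, slide_id, sep = "||"))
}
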