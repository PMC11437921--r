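#' Read and write pipeline tables as TSV
#'
#' Plain tab-separated interchange formats: sample metadata (`sample_id`,
#' `diagnosis`, `sex`, `age`, `role`, `batch`, `channel`), abundance
#' matrices (first column `protein_id`, one column per sample, missing
#' values as empty fields) and simulation truth (per-protein effect columns
#' plus one batch-shift column per batch).
#'
#' @param design,matrix,truth objects to write.
#' @param path file path.
#' @name tmt_io
NULL

#' @rdname tmt_io
#' @export
write_design <- function(design, path) {
  check_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname tmt_io
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  d$batch <- as.integer(d$batch)
  d$channel <- as.character(d$channel)
  check_design(d)
  d
}

#' @rdname tmt_io
#' @param scale scale of the matrix being read.
#' @export
write_abundance <- function(matrix, path) {
  if (!inherits(matrix, "abundance_matrix"))
    stop("'matrix' must be an abundance_matrix")
  df <- data.frame(protein_id = protein_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname tmt_io
#' @export
read_abundance <- function(path,
                           scale = c("raw", "log2_ratio",
                                     "log2_corrected")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  abundance_matrix(m, scale)
}

#' @rdname tmt_io
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "tmt_truth")) stop("'truth' must be a tmt_truth")
  df <- data.frame(protein_id = truth$protein_id,
                   baseline = truth$baseline,
                   effect = truth$effect,
                   is_differential = truth$is_differential,
                   sigma = truth$sigma,
                   truth$batch_shift,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
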