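#' Protein abundance matrix with an explicit scale state
#'
#' Container for a proteins x samples matrix of reporter abundances. The
#' `scale` field records where the matrix sits in the normalization chain:
#' `"raw"` (positive reporter intensities, missing values allowed),
#' `"log2_ratio"` (log2 of sample/master-pool ratios) or `"log2_corrected"`
#' (after empirical-Bayes batch correction). Scale transitions only move
#' forward: raw -> log2_ratio -> log2_corrected.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; must
#'   carry rownames (protein ids) and colnames (sample ids).
#' @param scale one of `"raw"`, `"log2_ratio"`, `"log2_corrected"`.
#' @return an object of class `abundance_matrix`: a list with elements
#'   `values` and `scale`.
#' @examples
#' m <- matrix(2^rnorm(6), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
#' abundance_matrix(m, "raw")
#' @export
abundance_matrix <- function(values,
                             scale = c("raw", "log2_ratio", "log2_corrected")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("protein and sample ids must be unique")
  if (scale == "raw") {
    if (any(values <= 0, na.rm = TRUE))
      stop("raw abundances must be strictly positive where present")
  } else if (anyNA(values)) {
    stop("missing values are only allowed on the raw scale")
  }
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Protein and sample identifiers of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return character vector of ids.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname protein_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0)
    cat(sprintf("  %d missing entries (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$values)))
  invisible(x)
}

# validate a design data.frame and (optionally) its agreement with a matrix
check_design <- function(design, mat = NULL) {
  need <- c("sample_id", "diagnosis", "sex", "age", "role", "batch", "channel")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("'design' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  bad <- !design$role %in% c("clinical", "master_pool", "qc")
  if (any(bad)) stop("unknown role: ", unique(design$role[bad])[1])
  if (!is.null(mat)) {
    missing_cols <- setdiff(sample_ids(mat), design$sample_id)
    if (length(missing_cols) > 0)
      stop("matrix columns absent from design: ",
           paste(utils::head(missing_cols, 3), collapse = ", "))
  }
  invisible(design)
}

# batch of each matrix column, as a factor
column_batches <- function(mat, design) {
  b <- design$batch[match(sample_ids(mat), design$sample_id)]
  if (anyNA(b)) stop("every matrix column needs a batch in the design")
  factor(b)
}
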