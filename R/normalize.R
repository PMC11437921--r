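#' Master-pool ratio normalization
#'
#' Divides every protein's raw abundance by the master-pool value of the
#' sample's batch and log2-transforms the ratio:
#' `value[p, s] = log2(raw[p, s] / raw[p, MP(batch(s))])`. Because the
#' master pool is measured in every batch, any additive per-(protein, batch)
#' log2 offset cancels exactly in the ratio. Master-pool columns are dropped
#' from the output; missing raw values propagate.
#'
#' @param raw a raw-scale [abundance_matrix()].
#' @param design sample metadata with exactly one master-pool entry per
#'   batch.
#' @return an `abundance_matrix` on the `log2_ratio` scale.
#' @export
mp_normalize <- function(raw, design) {
  if (!inherits(raw, "abundance_matrix") || raw$scale != "raw")
    stop("'raw' must be an abundance_matrix on the raw scale")
  check_design(design, raw)
  sid <- sample_ids(raw)
  role <- design$role[match(sid, design$sample_id)]
  batch <- design$batch[match(sid, design$sample_id)]
  out <- raw$values
  for (b in unique(batch)) {
    mp_col <- which(batch == b & role == "master_pool")
    if (length(mp_col) != 1)
      stop("batch ", b, " must have exactly one master-pool column")
    mp <- raw$values[, mp_col]
    bad <- is.na(mp) | mp <= 0
    cols <- which(batch == b)
    out[, cols] <- log2(raw$values[, cols] / mp)
    if (any(bad)) {
      warning(sum(bad), " protein(s) with missing/zero master-pool value",
              " in batch ", b, "; their entries in this batch set missing")
      out[bad, cols] <- NA_real_
    }
  }
  keep <- which(role != "master_pool")
  m <- out[, keep, drop = FALSE]
  structure(list(values = m, scale = "log2_ratio"),
            class = "abundance_matrix")
}

#' Complete-case protein filter
#'
#' Retains exactly the proteins with no missing value in any sample, in
#' their original order.
#'
#' @param matrix an [abundance_matrix()] on any scale.
#' @return an `abundance_matrix` with the incomplete rows removed.
#' @export
filter_complete <- function(matrix) {
  if (!inherits(matrix, "abundance_matrix"))
    stop("'matrix' must be an abundance_matrix")
  keep <- rowSums(is.na(matrix$values)) == 0
  structure(list(values = matrix$values[keep, , drop = FALSE],
                 scale = matrix$scale),
            class = "abundance_matrix")
}

#' Empirical-Bayes batch correction
#'
#' Removes residual per-batch location and scale effects from a complete
#' log2-ratio matrix with the parametric empirical-Bayes batch adjustment of
#' ComBat (per-protein standardization, batch-wise location/scale estimates
#' shrunk toward batch-level priors, then adjustment). No covariates are
#' included in the model: block randomization is relied upon to keep group
#' signal out of the batch estimates, and a note is emitted when diagnosis
#' groups are visibly unbalanced across batches.
#'
#' @param matrix a complete [abundance_matrix()] on the `log2_ratio` scale
#'   (run [filter_complete()] first).
#' @param design sample metadata; every batch needs at least 2 samples.
#' @return an `abundance_matrix` on the `log2_corrected` scale.
#' @export
combat_correct <- function(matrix, design) {
  if (!inherits(matrix, "abundance_matrix"))
    stop("'matrix' must be an abundance_matrix")
  if (matrix$scale != "log2_ratio")
    stop("batch correction expects the log2_ratio scale")
  if (anyNA(matrix$values))
    stop("matrix has missing values; run filter_complete() first")
  check_design(design, matrix)
  batch <- column_batches(matrix, design)
  if (any(table(batch) < 2))
    stop("every batch needs at least 2 samples for batch correction")
  diag <- design$diagnosis[match(sample_ids(matrix), design$sample_id)]
  keep_diag <- !is.na(diag)
  if (any(keep_diag)) {
    tab <- table(diag[keep_diag], droplevels(batch[keep_diag]))
    if (any(tab == 0) && nrow(tab) > 1 && ncol(tab) > 1)
      message("note: diagnosis groups are unbalanced across batches; ",
              "batch correction without covariates may absorb group signal")
  }

  if (nlevels(droplevels(batch)) == 1)            # nothing to correct
    return(structure(list(values = matrix$values, scale = "log2_corrected"),
                     class = "abundance_matrix"))

  x <- matrix$values
  v <- apply(x, 1, stats::var)
  flat <- v == 0
  if (any(flat))
    warning(sum(flat), " zero-variance protein(s) left unchanged")
  out <- x
  if (sum(!flat) > 0) {
    corrected <- suppressMessages(
      sva::ComBat(dat = x[!flat, , drop = FALSE], batch = batch))
    out[!flat, ] <- corrected
  }
  structure(list(values = out, scale = "log2_corrected"),
            class = "abundance_matrix")
}

#' QC-channel technical-variation metrics
#'
#' Per-protein coefficient of variation of the QC channels (SD divided by
#' mean after converting log2 values back to the original scale) and the
#' signal-to-noise ratio, SD of clinical log2 values over SD of QC log2
#' values. Sample SDs (n - 1 denominator) are used throughout. A protein
#' whose QC values are all equal gets `cv = 0` and an infinite `snr`
#' sentinel (with a warning); proteins with fewer than 2 QC observations get
#' `NA`.
#'
#' @param matrix an [abundance_matrix()] on a log2 scale.
#' @param design sample metadata; at least 2 QC and 2 clinical columns
#'   required.
#' @return data.frame with columns `protein_id`, `cv`, `sd_clinical`,
#'   `sd_qc`, `snr`.
#' @export
compute_qc_metrics <- function(matrix, design) {
  if (!inherits(matrix, "abundance_matrix") || matrix$scale == "raw")
    stop("'matrix' must be an abundance_matrix on a log2 scale")
  check_design(design, matrix)
  role <- design$role[match(sample_ids(matrix), design$sample_id)]
  qc_cols <- which(role == "qc")
  clin_cols <- which(role == "clinical")
  if (length(qc_cols) < 2)
    stop("at least 2 QC columns are required")
  if (length(clin_cols) < 2)
    stop("at least 2 clinical columns are required")
  qx <- matrix$values[, qc_cols, drop = FALSE]
  cx <- matrix$values[, clin_cols, drop = FALSE]
  n_qc <- rowSums(!is.na(qx))
  lin <- 2^qx
  cv <- apply(lin, 1, stats::sd, na.rm = TRUE) /
    rowMeans(lin, na.rm = TRUE)
  sd_qc <- apply(qx, 1, stats::sd, na.rm = TRUE)
  sd_clin <- apply(cx, 1, stats::sd, na.rm = TRUE)
  snr <- sd_clin / sd_qc
  zero_sd <- !is.na(sd_qc) & sd_qc == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd),
            " protein(s) with zero QC SD; snr reported as +Inf")
    snr[zero_sd] <- Inf
  }
  few <- n_qc < 2
  cv[few] <- sd_qc[few] <- snr[few] <- NA_real_
  data.frame(protein_id = protein_ids(matrix), cv = cv,
             sd_clinical = sd_clin, sd_qc = sd_qc, snr = snr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA diagnostic of batch structure
#'
#' Column-centered principal component analysis of the samples, used to
#' inspect batch clustering before and after correction.
#'
#' @param matrix a complete [abundance_matrix()].
#' @param design sample metadata (for batch labels in the output).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components), `var_frac` (variance fraction per component)
#'   and `batch` (per-sample batch labels).
#' @export
pca_batch_diagnostic <- function(matrix, design, n_components = 2) {
  if (!inherits(matrix, "abundance_matrix"))
    stop("'matrix' must be an abundance_matrix")
  if (anyNA(matrix$values)) stop("matrix must be complete")
  if (ncol(matrix$values) < 3) stop("need at least 3 samples")
  check_design(design, matrix)
  x <- t(matrix$values)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- svd(xc)
  k <- min(n_components, length(s$d))
  tot <- sum(s$d^2)
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k, k)
  if (tot == 0) {
    scores[] <- 0
    var_frac <- rep(0, k)
  } else var_frac <- (s$d^2 / tot)[seq_len(k)]
  rownames(scores) <- sample_ids(matrix)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- protein_ids(matrix)
  list(scores = scores, loadings = loadings, var_frac = var_frac,
       batch = column_batches(matrix, design))
}

#' Per-protein across-batch variance fraction
#'
#' One-way decomposition of each protein's variance into across-batch and
#' within-batch parts; returns the batch sum-of-squares divided by the total
#' sum-of-squares, a direct measure of residual batch effect.
#'
#' @param matrix a complete [abundance_matrix()].
#' @param design sample metadata.
#' @return numeric vector (one fraction per protein).
#' @export
batch_variance_fraction <- function(matrix, design) {
  if (anyNA(matrix$values)) stop("matrix must be complete")
  check_design(design, matrix)
  b <- column_batches(matrix, design)
  x <- matrix$values
  gm <- rowMeans(x)
  tot <- rowSums((x - gm)^2)
  bss <- numeric(nrow(x))
  for (lev in levels(b)) {
    cols <- which(b == lev)
    bm <- rowMeans(x[, cols, drop = FALSE])
    bss <- bss + length(cols) * (bm - gm)^2
  }
  out <- bss / tot
  out[tot == 0] <- 0
  stats::setNames(out, protein_ids(matrix))
}
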