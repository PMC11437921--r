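#' Mann-Whitney estimate of the ROC area
#'
#' Tie-aware probability that a positive-class value exceeds a negative-class
#' value: `[#(pos > neg) + 0.5 #(pos = neg)] / (n_pos * n_neg)`, computed
#' from midranks.
#'
#' @param values numeric vector of finite marker values.
#' @param labels logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' mann_whitney_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
#' @export
mann_whitney_auc <- function(values, labels) {
  pos <- as.logical(labels)
  if (length(values) != length(pos) || anyNA(pos))
    stop("'labels' must be a binary vector matching 'values'")
  if (!all(is.finite(values))) stop("'values' must be finite")
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be non-empty")
  r <- rank(values)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# stratified bootstrap column-index matrix: positives first in each column
.boot_indices <- function(pos, n_boot) {
  ip <- which(pos); ineg <- which(!pos)
  np <- length(ip); nn <- length(ineg)
  rbind(
    matrix(ip[sample.int(np, np * n_boot, replace = TRUE)], np, n_boot),
    matrix(ineg[sample.int(nn, nn * n_boot, replace = TRUE)], nn, n_boot))
}

#' Bootstrap ROC summary for one marker
#'
#' Stratified bootstrap of the Mann-Whitney AUC: each class is resampled
#' with replacement to its own size, the AUC recomputed for every resample,
#' and the mean and sample SD over `n_boot` resamples reported.
#'
#' @inheritParams mann_whitney_auc
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed; identical seeds give identical results.
#' @return named numeric vector `c(auc_mean, auc_sd)`.
#' @export
bootstrap_auc <- function(values, labels, n_boot = 500, seed = NULL) {
  pos <- as.logical(labels)
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("both classes need at least 2 members")
  if (n_boot < 2) stop("'n_boot' must be at least 2")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.null(seed)) set.seed(seed)
  idx <- .boot_indices(pos, n_boot)
  aucs <- cpp_auc_boot(matrix(values, nrow = 1), idx, sum(pos))[1, ]
  c(auc_mean = mean(aucs), auc_sd = stats::sd(aucs))
}

#' Permutation-based q-values from a threshold walk
#'
#' Estimates a false-discovery q-value for every protein from its observed
#' bootstrap mean AUC and the mean AUCs obtained after label permutation.
#' Two independent branches are walked: proteins with observed AUC above 0.5
#' (thresholds descending) and below 0.5 (ascending); at each threshold the
#' FDR estimate is the count of permuted AUCs at least as extreme divided by
#' the count of observed AUCs at least as extreme, clipped to `[0, 1]` and
#' monotonized so q never decreases towards less extreme proteins. Proteins
#' with AUC exactly 0.5 get q = 1.
#'
#' `permuted` may hold the concatenated results of several permutations (a
#' multiple of `length(observed)`); permuted counts are then scaled by the
#' number of permutations.
#'
#' @param observed per-protein observed mean AUC, in `[0, 1]`.
#' @param permuted per-protein mean AUC after label permutation.
#' @return numeric q-values aligned with `observed`.
#' @examples
#' permutation_qvalues(c(0.95, 0.7, 0.6), c(0.8, 0.55, 0.5))
#' @export
permutation_qvalues <- function(observed, permuted) {
  if (length(permuted) %% length(observed) != 0)
    stop("'permuted' length must be a multiple of 'observed' length")
  if (any(observed < 0 | observed > 1) || any(permuted < 0 | permuted > 1))
    stop("AUC values must lie in [0, 1]")
  n_perm <- length(permuted) / length(observed)
  q <- rep(1, length(observed))

  walk <- function(idx, lower) {
    o <- observed[idx]
    ord <- order(o, decreasing = !lower)   # most extreme first
    fdr <- vapply(o[ord], function(t) {
      n_obs <- if (lower) sum(observed <= t) else sum(observed >= t)
      n_null <- if (lower) sum(permuted <= t) else sum(permuted >= t)
      min(1, (n_null / n_perm) / n_obs)
    }, numeric(1))
    qv <- rev(cummin(rev(fdr)))            # min over less-extreme thresholds
    q[idx[ord]] <<- qv
  }
  up <- which(observed > 0.5)
  lo <- which(observed < 0.5)
  if (length(up)) walk(up, lower = FALSE)
  if (length(lo)) walk(lo, lower = TRUE)
  q
}

#' Bootstrap-ROC differential abundance across all proteins
#'
#' For every protein of a corrected, complete matrix: stratified bootstrap
#' ROC against the comparison labels (positive group vs a comparator group
#' or pooled union of groups), then the same computation after a global
#' label permutation (one permutation shared by all proteins, preserving
#' inter-protein correlation), and a permutation q-value from the threshold
#' walk of [permutation_qvalues()]. A protein is called `up` when its mean
#' AUC exceeds 0.5 at `q < q_cutoff`, `down` when below 0.5, otherwise
#' `null`.
#'
#' Bootstrap resample draws are shared across proteins within a comparison
#' (the labels, not the proteins, are resampled), which preserves the
#' correlation structure between proteins exactly as the global permutation
#' does.
#'
#' @param matrix a complete [abundance_matrix()] on a log2 scale.
#' @param design sample metadata.
#' @param positive diagnosis label of the positive class.
#' @param comparator character vector of diagnosis labels pooled as the
#'   negative class.
#' @param n_boot bootstrap resamples per protein.
#' @param q_cutoff q-value threshold for direction calls.
#' @param n_perm number of label permutations pooled into the null.
#' @param seed integer seed.
#' @return data.frame of class `roc_diff` with columns `protein_id`,
#'   `auc_mean`, `auc_sd`, `q_value`, `direction`, sorted by `q_value` then
#'   by `|auc_mean - 0.5|` descending.
#' @export
run_differential <- function(matrix, design, positive = "PSP",
                             comparator = c("PD", "HC"), n_boot = 500,
                             q_cutoff = 0.01, n_perm = 1, seed = NULL) {
  if (!inherits(matrix, "abundance_matrix") || matrix$scale == "raw")
    stop("'matrix' must be an abundance_matrix on a log2 scale")
  if (anyNA(matrix$values)) stop("matrix must be complete")
  check_design(design, matrix)
  if (length(comparator) == 0) stop("empty comparator group")
  known <- unique(design$diagnosis[design$role == "clinical"])
  bad <- setdiff(c(positive, comparator), known)
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "))

  diag <- design$diagnosis[match(sample_ids(matrix), design$sample_id)]
  use <- which(diag %in% c(positive, comparator))
  x <- matrix$values[, use, drop = FALSE]
  pos <- diag[use] == positive
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("both comparison classes need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)

  np <- sum(pos)
  obs <- cpp_auc_boot(x, .boot_indices(pos, n_boot), np)
  auc_mean <- rowMeans(obs)
  auc_sd <- apply(obs, 1, stats::sd)

  perm_means <- unlist(lapply(seq_len(n_perm), function(i) {
    perm_pos <- seq_along(pos) %in% sample.int(length(pos), np)
    rowMeans(cpp_auc_boot(x, .boot_indices(perm_pos, n_boot), np))
  }))

  q <- permutation_qvalues(auc_mean, perm_means)
  direction <- rep("null", nrow(x))
  direction[auc_mean > 0.5 & q < q_cutoff] <- "up"
  direction[auc_mean < 0.5 & q < q_cutoff] <- "down"

  out <- data.frame(protein_id = protein_ids(matrix),
                    auc_mean = auc_mean, auc_sd = auc_sd, q_value = q,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, -abs(out$auc_mean - 0.5)), ]
  rownames(out) <- NULL
  structure(out,
            class = c("roc_diff", "data.frame"),
            positive = positive, comparator = comparator,
            n_boot = n_boot, q_cutoff = q_cutoff)
}

#' @export
print.roc_diff <- function(x, n = 10, ...) {
  cat(sprintf("Bootstrap-ROC differential abundance: %s vs %s\n",
              attr(x, "positive"),
              paste(attr(x, "comparator"), collapse = "+")))
  cat(sprintf("  %d proteins, %d bootstrap resamples, q cutoff %g\n",
              nrow(x), attr(x, "n_boot"), attr(x, "q_cutoff")))
  cat(sprintf("  calls: %d up, %d down\n",
              sum(x$direction == "up"), sum(x$direction == "down")))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' @export
summary.roc_diff <- function(object, ...) {
  c(n_proteins = nrow(object),
    up = sum(object$direction == "up"),
    down = sum(object$direction == "down"),
    null = sum(object$direction == "null"))
}
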