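#' Simulate a raw multi-batch TMT abundance matrix with known truth
#'
#' Generates reporter abundances for every sample in a batch design on the
#' model
#' \deqn{raw = 2^{(baseline + effect \cdot 1[group] + shift_{pb} +
#'       \epsilon)}}{raw = 2^(baseline + effect*[in group] + shift + noise)}
#' where a random fraction of proteins carries a signed log2 group effect
#' (half up, half down) in the affected diagnosis group, each (protein,
#' batch) pair has an additive log2 shift, and each batch inflates noise by
#' a multiplicative factor. The master-pool channel of each batch measures
#' the per-protein mean of all clinical samples' true (noise-free)
#' abundances; QC channels share one fixed latent profile across batches and
#' carry technical noise only. Missing values are completely at random in
#' clinical and QC channels (never in the master pool).
#'
#' @param design sample metadata from [block_randomize()]; every batch must
#'   contain exactly one master-pool entry.
#' @param n_proteins number of proteins to simulate.
#' @param frac_differential fraction of proteins carrying a group effect.
#' @param delta absolute log2 effect size of differential proteins.
#' @param sigma residual SD of clinical log2 abundances (biological plus
#'   technical).
#' @param batch_shift_sd SD of the additive per-(protein, batch) log2 shift.
#' @param batch_scale_sd SD (log scale) of the per-batch multiplicative
#'   noise inflation.
#' @param qc_noise_sd technical noise SD (log2) of master-pool and QC
#'   measurements.
#' @param missing_rate probability that a clinical/QC raw value is missing.
#' @param affected_group diagnosis group carrying the effect.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log2 abundance.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements `matrix` (a raw [abundance_matrix()]) and
#'   `truth` (class `tmt_truth`: baseline, signed `effect`, differential
#'   flags, `sigma`, `batch_shift` matrix, `batch_scale`, QC latent profile).
#' @examples
#' design <- block_randomize(generate_cohort(n_per_group = 4, seed = 1),
#'                           n_batches = 2, channels = tmt11_channels()[1:8],
#'                           n_qc_batches = 1, seed = 1)
#' sim <- simulate_tmt(design, n_proteins = 50, seed = 1)
#' sim$matrix
#' @export
simulate_tmt <- function(design,
                         n_proteins = 1409,
                         frac_differential = 0.17,
                         delta = log2(1.35),
                         sigma = 0.338,
                         batch_shift_sd = 0.5,
                         batch_scale_sd = 0.1,
                         qc_noise_sd = 0.1,
                         missing_rate = 0.008,
                         affected_group = "PSP",
                         baseline_mean = 6,
                         baseline_sd = 2,
                         seed = NULL) {
  check_design(design)
  if (frac_differential < 0 || frac_differential > 1)
    stop("'frac_differential' must lie in [0, 1]")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  batches <- sort(unique(design$batch))
  mp_per_batch <- vapply(batches, function(b)
    sum(design$role == "master_pool" & design$batch == b), integer(1))
  if (any(mp_per_batch != 1L))
    stop("every batch needs exactly one master-pool entry")
  clinical <- design$role == "clinical"
  if (!any(clinical)) stop("design has no clinical samples")
  if (frac_differential > 0 && delta != 0 &&
      !affected_group %in% design$diagnosis[clinical])
    stop("affected group '", affected_group, "' absent from the design")
  if (!is.null(seed)) set.seed(seed)

  p <- n_proteins
  n_b <- length(batches)
  baseline <- stats::rnorm(p, baseline_mean, baseline_sd)
  n_da <- round(frac_differential * p)
  da_idx <- if (n_da > 0) sample.int(p, n_da) else integer(0)
  effect <- numeric(p)
  if (n_da > 0)
    effect[da_idx] <- sample(rep_len(c(1, -1), n_da)) * delta
  batch_shift <- matrix(stats::rnorm(p * n_b, 0, batch_shift_sd), p, n_b,
                        dimnames = list(NULL, paste0("batch_", batches)))
  batch_scale <- exp(stats::rnorm(n_b, 0, batch_scale_sd))
  qc_profile <- baseline + stats::rnorm(p, 0, sigma)

  # true (noise-free) log2 abundance of each clinical sample, and the
  # master pool as the mean of their un-logged values
  in_group <- design$diagnosis == affected_group & clinical
  mu_clin <- outer(baseline, rep(1, sum(clinical))) +
    outer(effect, as.numeric(in_group[clinical]))
  mp_true <- log2(rowMeans(2^mu_clin))

  ids <- sprintf("P%04d", seq_len(p))
  vals <- matrix(NA_real_, p, nrow(design),
                 dimnames = list(ids, design$sample_id))
  clin_cols <- which(clinical)
  for (j in seq_len(nrow(design))) {
    b <- match(design$batch[j], batches)
    shift <- batch_shift[, b]
    sc <- batch_scale[b]
    logv <- switch(design$role[j],
      clinical = {
        k <- match(j, clin_cols)
        mu_clin[, k] + shift + stats::rnorm(p, 0, sigma * sc)
      },
      master_pool = mp_true + shift + stats::rnorm(p, 0, qc_noise_sd * sc),
      qc = qc_profile + shift + stats::rnorm(p, 0, qc_noise_sd * sc))
    vals[, j] <- 2^logv
  }
  if (missing_rate > 0) {
    droppable <- which(design$role != "master_pool")
    miss <- matrix(stats::runif(p * length(droppable)) < missing_rate,
                   p, length(droppable))
    vals[, droppable][miss] <- NA_real_
  }

  truth <- structure(list(
    protein_id = ids,
    baseline = baseline,
    effect = effect,
    is_differential = effect != 0,
    sigma = rep.int(sigma, p),
    delta = delta,
    batch_shift = batch_shift,
    batch_scale = batch_scale,
    qc_profile = qc_profile,
    missing_rate = missing_rate,
    affected_group = affected_group
  ), class = "tmt_truth")

  list(matrix = abundance_matrix(vals, "raw"), truth = truth)
}

#' @export
print.tmt_truth <- function(x, ...) {
  cat(sprintf(
    "tmt_truth: %d proteins, %d differential (|delta| = %.3f), sigma = %.3f\n",
    length(x$effect), sum(x$is_differential), x$delta, x$sigma[1]))
  invisible(x)
}
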