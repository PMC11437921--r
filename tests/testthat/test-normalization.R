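test_that("mp_normalize computes log2 sample-to-pool ratios", {
  raw <- matrix(c(200, 50, 100, 100, 100, 100), nrow = 2,
                dimnames = list(c("P1", "P2"), c("s1", "s2", "MP")))
  w <- wrap_log2(raw, role = c("clinical", "clinical", "master_pool"),
                 scale = "raw")
  out <- mp_normalize(w$matrix, w$design)
  expect_equal(out$scale, "log2_ratio")
  expect_equal(sample_ids(out), c("s1", "s2"))
  expect_equal(out$values["P1", ], c(s1 = 1, s2 = 0))
  expect_equal(out$values["P2", ], c(s1 = -1, s2 = 0))
  # a column identical to its master pool normalizes to zero
  expect_true(all(out$values[, "s2"] == 0))
})

test_that("mp_normalize round-trips and cancels additive batch shifts", {
  design <- tiny_design()
  sim <- simulate_tmt(design, n_proteins = 80, batch_shift_sd = 1,
                      batch_scale_sd = 0, missing_rate = 0, seed = 2)
  lr <- mp_normalize(sim$matrix, design)
  # round trip: un-logged ratio equals raw / MP
  mp_ids <- design$sample_id[design$role == "master_pool"]
  b1_mp <- mp_ids[design$batch[match(mp_ids, design$sample_id)] == 1]
  b1_cols <- design$sample_id[design$batch == 1 &
                                design$role != "master_pool"]
  expect_equal(2^lr$values[, b1_cols],
               sim$matrix$values[, b1_cols] / sim$matrix$values[, b1_mp],
               tolerance = 1e-12)

  # in the noise-free limit the per-batch additive shift cancels exactly
  sim0 <- simulate_tmt(design, n_proteins = 50, frac_differential = 0,
                       sigma = 1e-9, qc_noise_sd = 1e-9,
                       batch_shift_sd = 1, batch_scale_sd = 0,
                       missing_rate = 0, seed = 3)
  lr0 <- mp_normalize(sim0$matrix, design)
  cl_ids <- clinical_rows(design)$sample_id
  per_protein_range <- apply(lr0$values[, cl_ids], 1,
                             function(v) diff(range(v)))
  expect_lt(max(per_protein_range), 1e-6)
})

test_that("mp_normalize flags absent or degenerate master pools", {
  design <- tiny_design()
  sim <- simulate_tmt(design, n_proteins = 10, missing_rate = 0, seed = 1)
  no_mp <- design[!(design$role == "master_pool" & design$batch == 1), ]
  m2 <- sim$matrix
  m2$values <- m2$values[, no_mp$sample_id]
  expect_error(mp_normalize(m2, no_mp), "master-pool")

  mp1 <- design$sample_id[design$role == "master_pool" &
                            design$batch == 1]
  m3 <- sim$matrix
  m3$values[3, mp1] <- NA
  expect_warning(out <- mp_normalize(m3, design), "master-pool")
  b1_cols <- intersect(sample_ids(out),
                       design$sample_id[design$batch == 1])
  expect_true(all(is.na(out$values[3, b1_cols])))
  expect_false(anyNA(out$values[4, b1_cols]))
})

test_that("filter_complete retains exactly the all-present rows", {
  m <- matrix(1:20 + 0.5, nrow = 5,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:4)))
  w <- wrap_log2(m)
  expect_identical(filter_complete(w$matrix)$values, m)

  m2 <- m; m2[2, 3] <- NA
  w2 <- wrap_log2(m2)
  out <- filter_complete(w2$matrix)
  expect_equal(nrow(out$values), 4)
  expect_equal(protein_ids(out), c("P1", "P3", "P4", "P5"))
  expect_false(anyNA(out$values))
})

test_that("filter_complete agrees with a direct recount on simulated dropout", {
  design <- tiny_design()
  sim <- simulate_tmt(design, n_proteins = 800, missing_rate = 0.02,
                      seed = 8)
  lr <- mp_normalize(sim$matrix, design)
  out <- filter_complete(lr)
  brute <- sum(apply(lr$values, 1, function(v) all(!is.na(v))))
  expect_equal(nrow(out$values), brute)
  expect_false(anyNA(out$values))
})

# two batches whose per-protein shift is proportional to the protein SD:
# every protein has the same standardized batch effect, so the parametric
# EB estimate is not shrunk and the location is removed exactly
shifted_two_batch <- function(seed = 3, resid_scale = 1, shift = 2) {
  set.seed(seed)
  p <- 40; n1 <- 20; n2 <- 20
  z1 <- rnorm(n1); z2 <- rnorm(n2)
  s_g <- runif(p, 0.5, 2)
  mu_g <- rnorm(p, 5)
  X <- matrix(0, p, n1 + n2,
              dimnames = list(sprintf("P%02d", 1:p),
                              sprintf("s%02d", 1:(n1 + n2))))
  for (g in 1:p) {
    e1 <- z1 + 1e-7 * rnorm(n1)
    e2 <- z2 + 1e-7 * rnorm(n2)
    X[g, ] <- mu_g[g] + s_g[g] * resid_scale * c(e1, e2) +
      s_g[g] * c(rep(0, n1), rep(shift, n2))
  }
  wrap_log2(X, batch = rep(1:2, c(n1, n2)))
}

test_that("combat_correct removes a pure location shift between batches", {
  w <- shifted_two_batch()
  out <- combat_correct(w$matrix, w$design)
  expect_equal(out$scale, "log2_corrected")
  m1 <- rowMeans(out$values[, w$design$batch == 1])
  m2 <- rowMeans(out$values[, w$design$batch == 2])
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), 1)), 1e-6)
  # grand mean preserved
  expect_equal(rowMeans(out$values), rowMeans(w$matrix$values),
               tolerance = 1e-8)
})

test_that("combat_correct is a no-op on a single batch and idempotent in the noise-free shift case", {
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("P", 1:6), paste0("s", 1:10)))
  w <- wrap_log2(m)
  out <- combat_correct(w$matrix, w$design)
  expect_equal(out$values, m)

  w2 <- shifted_two_batch(seed = 5, resid_scale = 1e-6)
  once <- combat_correct(w2$matrix, w2$design)
  again <- once; again$scale <- "log2_ratio"
  twice <- combat_correct(again, w2$design)
  expect_lt(max(abs(twice$values - once$values)), 1e-6)
})

test_that("combat_correct reduces the across-batch variance fraction of simulated shifts", {
  design <- mid_design()
  sim <- simulate_tmt(design, n_proteins = 300, frac_differential = 0,
                      batch_shift_sd = 0.5, missing_rate = 0, seed = 11)
  cc <- filter_complete(mp_normalize(sim$matrix, design))
  bc <- combat_correct(cc, design)
  before <- batch_variance_fraction(cc, design)
  after <- batch_variance_fraction(bc, design)
  expect_lt(median(after), 0.05)
  expect_lt(median(after), median(before))
  expect_gt(median(before), 0.10)
})

test_that("combat_correct enforces its preconditions", {
  design <- tiny_design()
  sim <- simulate_tmt(design, n_proteins = 20, missing_rate = 0.05,
                      seed = 2)
  lr <- mp_normalize(sim$matrix, design)
  expect_error(combat_correct(lr, design), "missing")
  expect_error(combat_correct(sim$matrix, design), "log2_ratio")

  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:10)))
  w <- wrap_log2(m, batch = c(rep(1L, 9), 2L))
  expect_error(combat_correct(w$matrix, w$design), "at least 2 samples")

  m2 <- rbind(m, P4 = rep(1, 10))
  w2 <- wrap_log2(m2, batch = rep(1:2, each = 5))
  expect_warning(out <- combat_correct(w2$matrix, w2$design),
                 "zero-variance")
  expect_equal(out$values["P4", ], m2["P4", ])
})

test_that("compute_qc_metrics follows the CV and S/N definitions", {
  # QC un-logged values {90, 100, 110}: cv = sample SD / mean = 0.1
  vals <- rbind(P1 = c(log2(90), log2(100), log2(110), 0.3, -0.1),
                P2 = c(0.2, 0.2, 0.2, 0.5, 0.1))
  colnames(vals) <- paste0("s", 1:5)
  w <- wrap_log2(vals, role = c("qc", "qc", "qc", "clinical", "clinical"))
  expect_warning(qm <- compute_qc_metrics(w$matrix, w$design), "zero QC SD")
  expect_equal(qm$cv[qm$protein_id == "P1"], sd(c(90, 100, 110)) / 100)
  expect_equal(qm$snr[qm$protein_id == "P1"],
               sd(c(0.3, -0.1)) / sd(c(log2(90), log2(100), log2(110))))
  # constant QC row: cv 0, snr +Inf sentinel
  expect_equal(qm$cv[qm$protein_id == "P2"], 0)
  expect_equal(qm$snr[qm$protein_id == "P2"], Inf)
})

test_that("most proteins clear S/N of 1 under the study noise profile", {
  design <- mid_design()
  sim <- simulate_tmt(design, n_proteins = 300, sigma = 0.338,
                      qc_noise_sd = 0.1, missing_rate = 0, seed = 12)
  lr <- mp_normalize(sim$matrix, design)
  qm <- compute_qc_metrics(lr, design)
  expect_gt(mean(qm$snr >= 1, na.rm = TRUE), 0.95)
})

test_that("QC and clinical CV distributions agree on technical-noise-only nulls", {
  # clinical dispersion set equal to the QC technical noise, batch effects
  # off; clinical CVs computed from one random column per batch so both
  # CV estimates use the same number of observations
  wins <- 0
  for (s in 1:10) {
    design <- mid_design(seed = s)
    sim <- simulate_tmt(design, n_proteins = 300, frac_differential = 0,
                        sigma = 0.2, qc_noise_sd = 0.2,
                        batch_shift_sd = 0, batch_scale_sd = 0,
                        missing_rate = 0, seed = 100 + s)
    lr <- mp_normalize(sim$matrix, design)
    role <- design$role[match(sample_ids(lr), design$sample_id)]
    batch <- design$batch[match(sample_ids(lr), design$sample_id)]
    qc_cols <- which(role == "qc")
    set.seed(200 + s)
    clin_cols <- vapply(unique(batch), function(b) {
      cand <- which(role == "clinical" & batch == b)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    cv_of <- function(cols) {
      lin <- 2^lr$values[, cols, drop = FALSE]
      apply(lin, 1, sd) / rowMeans(lin)
    }
    p <- suppressWarnings(ks.test(cv_of(qc_cols), cv_of(clin_cols))$p.value)
    if (p > 0.01) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("pca_batch_diagnostic behaves on degenerate and structured input", {
  m <- matrix(rep(c(1, 2, 3), 4), nrow = 3,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
  w <- wrap_log2(m)
  out <- pca_batch_diagnostic(w$matrix, w$design)
  expect_true(all(out$scores == 0))

  # full-rank reconstruction: scores %*% t(loadings) = centered matrix
  set.seed(4)
  m2 <- matrix(rnorm(80), 8, 10,
               dimnames = list(paste0("P", 1:8), paste0("s", 1:10)))
  w2 <- wrap_log2(m2, batch = rep(1:2, each = 5))
  full <- pca_batch_diagnostic(w2$matrix, w2$design, n_components = 10)
  xc <- scale(t(m2), center = TRUE, scale = FALSE)
  expect_equal(full$scores %*% t(full$loadings), unclass(xc),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lte(sum(full$var_frac), 1 + 1e-12)
})

test_that("batch clustering in PCA space weakens after correction", {
  skip_if_not_installed("cluster")
  design <- mid_design()
  sim <- simulate_tmt(design, n_proteins = 200, frac_differential = 0,
                      batch_shift_sd = 0.8, missing_rate = 0, seed = 13)
  cc <- filter_complete(mp_normalize(sim$matrix, design))
  bc <- combat_correct(cc, design)
  sil <- function(mat) {
    p <- pca_batch_diagnostic(mat, design)
    mean(cluster::silhouette(as.integer(p$batch),
                             dist(p$scores))[, "sil_width"])
  }
  expect_lt(sil(bc), sil(cc))
})
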