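# small batch designs reused across test files

tiny_design <- function(n_per_group = 4, n_batches = 2,
                        channels = tmt11_channels()[1:8],
                        n_qc_batches = 1, seed = 1) {
  block_randomize(generate_cohort(n_per_group = n_per_group, seed = seed),
                  n_batches = n_batches, channels = channels,
                  n_qc_batches = n_qc_batches, seed = seed)
}

# 36 clinical samples in 4 full 11-plex batches, QC in every batch
mid_design <- function(seed = 1) {
  block_randomize(generate_cohort(n_per_group = 12, seed = seed),
                  n_batches = 4, channels = tmt11_channels(),
                  n_qc_batches = 4, seed = seed)
}

# the full study layout: 120 clinical, 13 x 11-plex, QC in 10 batches
study_design <- function(seed = 1) {
  block_randomize(generate_cohort(seed = seed), seed = seed)
}

clinical_rows <- function(design) design[design$role == "clinical", ]

# wrap a bare matrix as a log2-scale abundance_matrix with a minimal design
wrap_log2 <- function(values, batch = NULL, role = "clinical",
                      diagnosis = NA_character_,
                      scale = "log2_ratio") {
  n <- ncol(values)
  if (is.null(batch)) batch <- rep(1L, n)
  design <- data.frame(
    sample_id = colnames(values),
    diagnosis = rep_len(diagnosis, n),
    sex = NA_character_, age = NA_real_,
    role = rep_len(role, n),
    batch = batch,
    channel = as.character(seq_len(n)),
    stringsAsFactors = FALSE)
  list(matrix = structure(list(values = values, scale = scale),
                          class = "abundance_matrix"),
       design = design)
}
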