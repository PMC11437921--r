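#' Default cohort demographics
#'
#' Per-group demographic parameters used as defaults by [generate_cohort()]:
#' three diagnosis groups (progressive supranuclear palsy, Parkinson's
#' disease, healthy controls) of 40 subjects each, with group mean ages and
#' female proportions typical of a matched CSF biomarker cohort. The age SD
#' of 7.1 years corresponds to a 95% CI half-width of about 2.2 years around
#' a group mean at n = 40.
#'
#' @return data.frame with columns `group`, `n`, `age_mean`, `age_sd`,
#'   `female_prop`.
#' @export
default_demographics <- function() {
  data.frame(
    group = c("PSP", "PD", "HC"),
    n = c(40L, 40L, 40L),
    age_mean = c(68.8, 64.1, 67.7),
    age_sd = c(7.1, 7.1, 7.1),
    female_prop = c(0.600, 0.475, 0.675),
    stringsAsFactors = FALSE
  )
}

#' Ordered 11-plex TMT channel labels
#'
#' The standard channel order of an 11-plex TMT kit; the master pool is
#' always placed in the last channel (131C).
#' @return character vector of length 11.
#' @export
tmt11_channels <- function() {
  c("126", "127N", "127C", "128N", "128C",
    "129N", "129C", "130N", "130C", "131", "131C")
}

#' Generate a clinical cohort with group-specific demographics
#'
#' Draws a cohort of clinical samples for the three diagnosis groups with
#' normally distributed ages (truncated at `age_min`) and Bernoulli sexes.
#' Batch and channel are left unassigned (`NA`) until [block_randomize()].
#'
#' @param n_per_group number of samples in each diagnosis group.
#' @param groups diagnosis labels.
#' @param age_mean named numeric, mean age (years) per group.
#' @param age_sd age SD in years (scalar or named per group).
#' @param female_prop named numeric in `[0, 1]`, proportion of females per
#'   group.
#' @param age_min minimum plausible age; normal draws are floored here.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return data.frame of clinical sample metadata with columns `sample_id`,
#'   `diagnosis`, `sex`, `age`, `role`, `batch`, `channel`.
#' @examples
#' cohort <- generate_cohort(n_per_group = 40, seed = 1)
#' table(cohort$diagnosis)
#' @export
generate_cohort <- function(n_per_group = 40,
                            groups = c("PSP", "PD", "HC"),
                            age_mean = NULL,
                            age_sd = NULL,
                            female_prop = NULL,
                            age_min = 18,
                            seed = NULL) {
  if (length(n_per_group) != 1 || n_per_group < 1 ||
      n_per_group != round(n_per_group))
    stop("'n_per_group' must be a positive integer")
  dem <- default_demographics()
  if (is.null(age_mean))
    age_mean <- stats::setNames(dem$age_mean, dem$group)[groups]
  if (is.null(age_sd))
    age_sd <- stats::setNames(dem$age_sd, dem$group)[groups]
  if (is.null(female_prop))
    female_prop <- stats::setNames(dem$female_prop, dem$group)[groups]
  age_mean <- rep_len(unname(age_mean[groups]), length(groups))
  age_sd <- rep_len(unname(if (!is.null(names(age_sd))) age_sd[groups]
                           else age_sd), length(groups))
  fp <- rep_len(unname(if (!is.null(names(female_prop))) female_prop[groups]
                       else female_prop), length(groups))
  if (anyNA(age_mean) || anyNA(age_sd) || anyNA(fp))
    stop("demographic parameters must cover every group")
  if (any(fp < 0 | fp > 1))
    stop("'female_prop' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    data.frame(
      sample_id = NA_character_,
      diagnosis = groups[g],
      sex = ifelse(stats::runif(n_per_group) < fp[g], "F", "M"),
      age = pmax(age_min, stats::rnorm(n_per_group, age_mean[g], age_sd[g])),
      role = "clinical",
      batch = NA_integer_,
      channel = NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  out$sample_id <- sprintf("S%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# total imbalance score of an assignment: squared deviation of per-batch
# female counts from proportional allocation plus squared standardized
# per-batch age means
.balance_score <- function(fem_cnt, age_sum, n_b, p_female, mu_age, sd_age) {
  z <- (age_sum / n_b - mu_age) / sd_age
  sum((fem_cnt - n_b * p_female)^2) + sum(z^2)
}

#' Block-randomize a cohort into TMT batches
#'
#' Assigns clinical samples to batches and channels so that diagnosis, sex
#' and age stay balanced across batches, then adds one master-pool entry per
#' batch (always in the last channel) and a QC entry in `n_qc_batches`
#' randomly chosen batches (random non-master-pool channel).
#'
#' Diagnosis balance is guaranteed constructively: per-group batch quotas are
#' obtained by largest-remainder rounding of the proportional allocation, so
#' each batch's group count differs from the ideal by less than one.
#' Individuals are then placed into the quota slots by a randomized greedy
#' pass minimizing a sex/age imbalance score (squared deviation of per-batch
#' female counts from proportional allocation plus squared standardized
#' per-batch mean ages), refined by pairwise swaps, with `n_restarts`
#' restarts keeping the best score.
#'
#' @param cohort data.frame from [generate_cohort()] (clinical rows only).
#' @param n_batches number of TMT batches.
#' @param channels ordered channel labels; the last is reserved for the
#'   master pool.
#' @param n_qc_batches number of batches that receive a QC channel.
#' @param seed integer seed.
#' @param n_restarts greedy restarts for the sex/age refinement.
#' @param n_swaps pairwise-swap refinement attempts per restart.
#' @return data.frame of sample metadata: the cohort with `batch`/`channel`
#'   filled in, plus added `master_pool` and `qc` rows (no diagnosis, sex or
#'   age).
#' @examples
#' design <- block_randomize(generate_cohort(seed = 1), seed = 1)
#' table(design$role)
#' @export
block_randomize <- function(cohort,
                            n_batches = 13,
                            channels = tmt11_channels(),
                            n_qc_batches = 10,
                            seed = NULL,
                            n_restarts = 50,
                            n_swaps = 400) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("'cohort' must be a non-empty data.frame")
  if (!all(cohort$role == "clinical"))
    stop("'cohort' must contain clinical samples only")
  if (n_qc_batches > n_batches)
    stop("'n_qc_batches' cannot exceed 'n_batches'")
  n <- nrow(cohort)
  n_ch <- length(channels)
  if (n + n_batches + n_qc_batches > n_batches * n_ch)
    stop("infeasible design: ", n, " clinical + ", n_batches,
         " master-pool + ", n_qc_batches, " QC slots exceed ",
         n_batches * n_ch, " channel slots")
  if (!is.null(seed)) set.seed(seed)

  qc_batches <- sort(sample.int(n_batches, n_qc_batches))
  cap <- rep.int(n_ch - 1L, n_batches)          # MP takes the last channel
  cap[qc_batches] <- cap[qc_batches] - 1L

  # water-filling: spread clinical samples as evenly as capacity allows
  sizes <- integer(n_batches)
  rem <- n
  while (rem > 0) {
    open <- which(sizes < cap)
    open <- open[order(sizes[open])]
    take <- open[seq_len(min(rem, length(open)))]
    sizes[take] <- sizes[take] + 1L
    rem <- rem - length(take)
  }

  groups <- sort(unique(cohort$diagnosis))
  n_g <- table(factor(cohort$diagnosis, levels = groups))
  ideal <- outer(sizes, as.numeric(n_g)) / n     # batches x groups
  quota <- floor(ideal)
  frac <- ideal - quota
  rem_row <- sizes - rowSums(quota)
  rem_col <- as.numeric(n_g) - colSums(quota)
  while (sum(rem_row) > 0) {
    feasible <- outer(rem_row > 0, rem_col > 0, "&")
    cand <- which(feasible & frac > -1, arr.ind = TRUE)
    if (nrow(cand) == 0) cand <- which(feasible, arr.ind = TRUE)
    pick <- cand[which.max(frac[cand]), , drop = FALSE]
    quota[pick] <- quota[pick] + 1L
    frac[pick] <- -2                             # each cell bumped once
    rem_row[pick[1]] <- rem_row[pick[1]] - 1L
    rem_col[pick[2]] <- rem_col[pick[2]] - 1L
  }

  is_f <- cohort$sex == "F"
  p_female <- mean(is_f)
  mu_age <- mean(cohort$age)
  sd_age <- stats::sd(cohort$age)
  if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
  g_idx <- match(cohort$diagnosis, groups)

  best_assign <- NULL
  best_score <- Inf
  for (r in seq_len(n_restarts)) {
    slots <- quota
    batch_of <- integer(n)
    fem_cnt <- numeric(n_batches)
    age_sum <- numeric(n_batches)
    cnt <- numeric(n_batches)
    for (i in sample.int(n)) {
      open <- which(slots[, g_idx[i]] > 0)
      if (length(open) > 1) {
        sc <- vapply(open, function(b) {
          nf <- fem_cnt[b] + is_f[i]
          nc <- cnt[b] + 1
          (nf - nc * p_female)^2 +
            ((age_sum[b] + cohort$age[i]) / nc - mu_age)^2 / sd_age^2
        }, numeric(1))
        b <- open[which.min(sc)]
      } else b <- open
      batch_of[i] <- b
      slots[b, g_idx[i]] <- slots[b, g_idx[i]] - 1L
      fem_cnt[b] <- fem_cnt[b] + is_f[i]
      age_sum[b] <- age_sum[b] + cohort$age[i]
      cnt[b] <- cnt[b] + 1
    }
    score <- .balance_score(fem_cnt, age_sum, sizes, p_female, mu_age, sd_age)
    # pairwise swaps within a diagnosis group across batches
    for (k in seq_len(n_swaps)) {
      i <- sample.int(n, 1)
      same <- which(g_idx == g_idx[i] & batch_of != batch_of[i])
      if (length(same) == 0) next
      j <- same[sample.int(length(same), 1)]
      bi <- batch_of[i]; bj <- batch_of[j]
      fem2 <- fem_cnt; age2 <- age_sum
      fem2[bi] <- fem2[bi] - is_f[i] + is_f[j]
      fem2[bj] <- fem2[bj] - is_f[j] + is_f[i]
      age2[bi] <- age2[bi] - cohort$age[i] + cohort$age[j]
      age2[bj] <- age2[bj] - cohort$age[j] + cohort$age[i]
      s2 <- .balance_score(fem2, age2, sizes, p_female, mu_age, sd_age)
      if (s2 < score) {
        score <- s2
        fem_cnt <- fem2; age_sum <- age2
        batch_of[i] <- bj; batch_of[j] <- bi
      }
    }
    if (score < best_score) {
      best_score <- score
      best_assign <- batch_of
    }
  }

  out <- cohort
  out$batch <- best_assign
  mp_channel <- channels[n_ch]
  extra <- list()
  for (b in seq_len(n_batches)) {
    free <- channels[-n_ch]
    if (b %in% qc_batches) {
      qc_ch <- sample(free, 1)
      free <- setdiff(free, qc_ch)
      extra[[length(extra) + 1L]] <- data.frame(
        sample_id = sprintf("QC_b%02d", b), diagnosis = NA_character_,
        sex = NA_character_, age = NA_real_, role = "qc",
        batch = b, channel = qc_ch, stringsAsFactors = FALSE)
    }
    extra[[length(extra) + 1L]] <- data.frame(
      sample_id = sprintf("MP_b%02d", b), diagnosis = NA_character_,
      sex = NA_character_, age = NA_real_, role = "master_pool",
      batch = b, channel = mp_channel, stringsAsFactors = FALSE)
    members <- which(out$batch == b)
    out$channel[members] <- sample(free, length(members))
  }
  res <- rbind(out, do.call(rbind, extra))
  res <- res[order(res$batch, match(res$channel, channels)), ]
  rownames(res) <- NULL
  res
}
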