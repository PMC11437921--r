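# independent reference implementations used as oracles

# AUC over all (positive, negative) pairs with half credit for ties
pairwise_auc <- function(values, pos) {
  vp <- values[pos]; vn <- values[!pos]
  s <- 0
  for (a in vp) for (b in vn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(vp) * length(vn))
}

# direct double-loop threshold walk for the permutation q-value
brute_qvalues <- function(observed, permuted) {
  q <- rep(1, length(observed))
  for (i in seq_along(observed)) {
    o <- observed[i]
    if (o == 0.5) next
    upper <- o > 0.5
    # best FDR achievable at this protein's threshold or any less extreme
    less_extreme <- if (upper) observed <= o & observed > 0.5
    else observed >= o & observed < 0.5
    q[i] <- min(vapply(observed[less_extreme], function(t) {
      n_obs <- if (upper) sum(observed >= t) else sum(observed <= t)
      n_null <- if (upper) sum(permuted >= t) else sum(permuted <= t)
      min(1, n_null / n_obs)
    }, numeric(1)))
  }
  q
}

# hypergeometric upper-tail probability from binomial coefficients
tail_sum_p <- function(overlap, set_size, query_size, bg_size) {
  k <- seq(overlap, min(set_size, query_size))
  sum(choose(set_size, k) * choose(bg_size - set_size, query_size - k)) /
    choose(bg_size, query_size)
}
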