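#' Univariate bootstrap ROC with percentile confidence interval
#'
#' Stratified bootstrap of the Mann-Whitney AUC with a 2.5/97.5 percentile
#' confidence interval. Following the usual classification convention the
#' reported AUC is oriented to be at least 0.5; the original direction
#' (`"up"` when higher values mark the positive class) is returned
#' separately.
#'
#' @inheritParams bootstrap_auc
#' @return list with `auc_mean`, `ci_low`, `ci_high`, `direction`.
#' @export
univariate_roc_ci <- function(values, labels, n_boot = 500, seed = NULL) {
  pos <- as.logical(labels)
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("both classes need at least 2 members")
  point <- mann_whitney_auc(values, pos)
  direction <- if (point < 0.5) "down" else "up"
  v <- if (direction == "down") -values else values
  if (!is.null(seed)) set.seed(seed)
  idx <- .boot_indices(pos, n_boot)
  aucs <- cpp_auc_boot(matrix(v, nrow = 1), idx, sum(pos))[1, ]
  ci <- unname(stats::quantile(aucs, c(0.025, 0.975)))
  list(auc_mean = mean(aucs), ci_low = ci[1], ci_high = ci[2],
       direction = direction)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis for a binary outcome,
#' computed by NIPALS-style sequential extraction of latent variables
#' maximizing covariance with the class label, with X-deflation between
#' components. Features are standardized internally (mean 0, SD 1);
#' zero-variance features are dropped with a warning. Class prediction
#' thresholds the continuous PLS score at the midpoint of the training-set
#' class mean scores.
#'
#' @param X numeric matrix, samples x features, with feature colnames.
#' @param y binary response (0/1, logical, or 2-level factor whose second
#'   level is the positive class).
#' @param n_components number of latent variables (default 2).
#' @return object of class `plsda` with unit-norm `weights`, `loadings`,
#'   orthogonal `scores`, `y_loadings`, per-component explained y-variance
#'   `r2y`, regression coefficients and the classification threshold.
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- .as_binary(y)
  if (length(y) != nrow(X)) stop("'y' must match rows of 'X'")
  if (length(unique(y)) < 2) stop("'y' must contain both classes")
  if (n_components < 1) stop("'n_components' must be at least 1")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0) stop("no usable features")
  centers <- colMeans(X)
  Xs <- scale(X, center = centers, scale = sds)
  yc <- y - mean(y)
  ss_y_tot <- sum(yc^2)

  p <- ncol(Xs)
  A <- n_components
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, nrow(Xs), A)
  qv <- numeric(A)
  Xd <- Xs; yd <- yc
  a_used <- 0
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                 # rank exhausted
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; qv[a] <- qa
    a_used <- a
  }
  if (a_used == 0) stop("X has no usable variation")
  if (a_used < A)
    warning("rank of X supports only ", a_used, " component(s)")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; qv <- qv[keep]
  ss_y <- qv^2 * colSums(Tm^2)            # y-variance captured per component

  beta <- W %*% solve(crossprod(P, W), qv)
  fitted_score <- as.numeric(Xs %*% beta) + mean(y)
  m0 <- mean(fitted_score[y == 0]); m1 <- mean(fitted_score[y == 1])
  structure(list(
    weights = W, loadings = P, scores = Tm, y_loadings = qv,
    r2y = if (ss_y_tot > 0) ss_y / ss_y_tot else rep(0, a_used),
    ss_y = ss_y, coefficients = beta,
    centers = centers, scales = sds, y_mean = mean(y),
    threshold = (m0 + m1) / 2, positive_high = m1 >= m0,
    n_components = a_used, features = colnames(Xs)
  ), class = "plsda")
}

.as_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("'y' must have exactly 2 levels")
    as.numeric(y == levels(y)[2])
  } else if (is.logical(y)) as.numeric(y)
  else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("'y' must be coded 0/1")
    y
  }
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d features, %d component(s)\n",
              length(x$features), x$n_components))
  cat("  explained y-variance per component:",
      paste(sprintf("%.3f", x$r2y), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) {
  stats::setNames(as.numeric(object$coefficients), object$features)
}

#' Predict from a PLS-DA model
#'
#' @param object fitted [plsda_fit()] model.
#' @param newdata samples x features matrix containing the model's features.
#' @param type `"score"` for the continuous PLS score, `"class"` for 0/1
#'   calls at the training threshold.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  newdata <- newdata[, object$features, drop = FALSE]
  Xs <- scale(newdata, center = object$centers, scale = object$scales)
  score <- as.numeric(Xs %*% object$coefficients) + object$y_mean
  if (type == "score") return(score)
  if (object$positive_high) as.numeric(score > object$threshold)
  else as.numeric(score < object$threshold)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` for unit-norm weight
#' columns, where `SS_a` is the y-variance captured by component `a` and `p`
#' the number of features. Satisfies `sum_j VIP_j^2 = p`.
#'
#' @param model fitted [plsda_fit()] model.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda")) stop("'model' must be a plsda fit")
  ss <- model$ss_y
  if (sum(ss) <= 0) stop("model explains no y-variance")
  p <- nrow(model$weights)
  vip <- sqrt(p * as.numeric(model$weights^2 %*% ss) / sum(ss))
  stats::setNames(vip, model$features)
}

#' Balanced Monte-Carlo cross-validation of PLS-DA feature panels
#'
#' Repeated stratified 2/3 train / 1/3 validation splits. In each iteration
#' a PLS-DA model on all features ranks them by VIP; for each requested
#' feature count `k` the top-k panel is refit and scored on the validation
#' third. Accuracies are averaged over iterations; validation scores are
#' pooled across iterations into one ROC per `k`, with a 2.5/97.5 percentile
#' interval of the per-iteration AUCs. Per-feature average importance is the
#' mean VIP from the ranking fits (over all iterations, or only over
#' iterations where the feature entered the top panel).
#'
#' @param X samples x features matrix.
#' @param y binary response (see [plsda_fit()]).
#' @param feature_counts integer vector of panel sizes `k`.
#' @param n_iter number of Monte-Carlo iterations.
#' @param n_components latent variables per fit (capped at `k`).
#' @param importance_over `"all"` or `"selected"` iterations.
#' @param seed integer master seed; per-iteration draws follow a fixed
#'   order from one stream.
#' @return object of class `mccv_report`: `metrics` (per-k accuracy, pooled
#'   AUC, CI), `importance` (per-feature mean VIP and selection frequency in
#'   the best panel), `best_k` (smallest k attaining maximal accuracy).
#' @export
mccv_evaluate <- function(X, y, feature_counts = c(2, 3, 5, 10, 20, 53),
                          n_iter = 50, n_components = 2,
                          importance_over = c("all", "selected"),
                          seed = NULL) {
  importance_over <- match.arg(importance_over)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- .as_binary(y)
  feature_counts <- sort(unique(as.integer(feature_counts)))
  if (max(feature_counts) > ncol(X))
    stop("largest feature count exceeds available features")
  if (min(table(y)) < 3) stop("both classes need at least 3 samples")
  if (!is.null(seed)) set.seed(seed)

  p <- ncol(X); feats <- colnames(X)
  kmax <- max(feature_counts)
  acc <- auc_iter <- matrix(NA_real_, n_iter, length(feature_counts))
  vip_mat <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, feats))
  in_top <- matrix(FALSE, n_iter, p, dimnames = list(NULL, feats))
  pooled <- lapply(feature_counts, function(k)
    list(score = numeric(0), y = numeric(0)))

  for (it in seq_len(n_iter)) {
    tr <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(2 / 3 * length(idx)))
    }))
    va <- setdiff(seq_along(y), tr)
    rank_fit <- plsda_fit(X[tr, , drop = FALSE], y[tr],
                          n_components = min(n_components, p))
    vip <- rep(0, p); names(vip) <- feats
    vip[names(vip_scores(rank_fit))] <- vip_scores(rank_fit)
    vip_mat[it, ] <- vip
    ranked <- feats[order(-vip, feats)]    # stable ties by feature id
    in_top[it, ranked[seq_len(kmax)]] <- TRUE
    for (ki in seq_along(feature_counts)) {
      k <- feature_counts[ki]
      panel <- ranked[seq_len(k)]
      fit <- plsda_fit(X[tr, panel, drop = FALSE], y[tr],
                       n_components = min(n_components, k))
      sc <- predict(fit, X[va, panel, drop = FALSE], type = "score")
      cl <- predict(fit, X[va, panel, drop = FALSE], type = "class")
      acc[it, ki] <- mean(cl == y[va])
      ori <- if (fit$positive_high) sc else -sc
      auc_iter[it, ki] <- mann_whitney_auc(ori, y[va] == 1)
      pooled[[ki]]$score <- c(pooled[[ki]]$score, ori)
      pooled[[ki]]$y <- c(pooled[[ki]]$y, y[va])
    }
  }

  metrics <- data.frame(
    k = feature_counts,
    accuracy = colMeans(acc),
    auc = vapply(pooled, function(pl)
      mann_whitney_auc(pl$score, pl$y == 1), numeric(1)),
    ci_low = apply(auc_iter, 2, stats::quantile, probs = 0.025),
    ci_high = apply(auc_iter, 2, stats::quantile, probs = 0.975),
    row.names = NULL)
  best_k <- feature_counts[which.max(metrics$accuracy)]

  sel_freq <- colMeans(in_top)
  mean_vip <- if (importance_over == "all") colMeans(vip_mat)
  else {
    mv <- colSums(vip_mat * in_top) / pmax(colSums(in_top), 1)
    mv[colSums(in_top) == 0] <- 0
    mv
  }
  importance <- data.frame(feature = feats, mean_vip = unname(mean_vip),
                           selection_frequency = unname(sel_freq),
                           row.names = NULL, stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_vip, importance$feature), ]
  rownames(importance) <- NULL

  structure(list(metrics = metrics, importance = importance,
                 best_k = best_k, n_iter = n_iter,
                 feature_counts = feature_counts),
            class = "mccv_report")
}

#' @export
print.mccv_report <- function(x, ...) {
  cat(sprintf("MCCV PLS-DA report: %d iterations, best k = %d (accuracy %.1f%%)\n",
              x$n_iter, x$best_k,
              100 * max(x$metrics$accuracy)))
  print(x$metrics, digits = 3)
  cat("top features by mean VIP:\n")
  print(utils::head(x$importance, 5), digits = 3)
  invisible(x)
}

#' @export
plot.mccv_report <- function(x, ...) {
  plot(x$metrics$k, 100 * x$metrics$accuracy, type = "b", pch = 19,
       xlab = "number of features", ylab = "predictive accuracy (%)", ...)
  graphics::abline(v = x$best_k, lty = 2, col = "grey50")
  invisible(x)
}

#' PCA scores and loadings for biplots
#'
#' Column-centered singular value decomposition: scores are the left
#' singular vectors scaled by the singular values, loadings are orthonormal,
#' and each component's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param X complete samples x features matrix with at least 3 samples.
#' @return list with `scores`, `loadings`, `var_frac`.
#' @export
pca_scores_loadings <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  if (nrow(X) < 3) stop("need at least 3 samples")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < .Machine$double.eps * 100))
    stop("degenerate input: all samples identical")
  s <- svd(Xc)
  flip <- vapply(seq_along(s$d), function(a) {
    l <- s$v[, a]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(s$u %*% diag(s$d, length(s$d)), 2, flip, `*`)
  loadings <- sweep(s$v, 2, flip, `*`)
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  list(scores = scores, loadings = loadings,
       var_frac = s$d^2 / sum(s$d^2))
}
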