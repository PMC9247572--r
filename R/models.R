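#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' AUC = (R1 - n1(n1+1)/2) / (n1 n0) with R1 the rank sum of positive-class
#' scores; ties count one half.  Invariant under strictly monotone score
#' transforms.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   second factor level / TRUE / 1 is the positive class).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest state classification with permutation importances
#'
#' Features (ASVs) are z-scored, samples are split into stratified train and
#' held-out sets, and a random forest is grown on the training split.  MDA is
#' the mean out-of-bag accuracy decrease under per-feature permutation, MDG
#' the total Gini impurity decrease (both via `randomForest::importance`);
#' ROC and AUC come from held-out class probabilities only.
#'
#' @param table A `normalized_table`, [count_table], or feature-by-sample
#'   matrix.
#' @param states Two-level per-sample labels.
#' @param n_trees Number of trees.
#' @param train_fraction Fraction of samples (per class) used for training.
#' @param seed Integer seed (controls split and forest).
#' @param top_k Size of the reported top-feature list.
#' @return Object of class `classifier_report`: `importance` (data frame
#'   `feature`, `mda`, `mdg`, `rank_mda`, `rank_mdg`), `top_features`,
#'   `roc` (data frame `fpr`, `tpr`), `auc`, `train_fraction`, `seed`.
#' @export
rf_classify <- function(table, states, n_trees = 500, train_fraction = 0.8,
                        seed = 1, top_k = 20) {
  x <- if (inherits(table, "normalized_table")) table$values
       else if (inherits(table, "count_table")) table$counts
       else as.matrix(table)
  states <- droplevels(as.factor(states))
  if (nlevels(states) != 2) stop("exactly two states required")
  sds <- apply(x, 1, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  feat <- t(z) # samples x features
  colnames(feat) <- rownames(x)

  set.seed(seed)
  train <- logical(nrow(feat))
  for (lv in levels(states)) {
    idx <- which(states == lv)
    train[sample(idx, max(1, round(train_fraction * length(idx))))] <- TRUE
  }
  if (length(unique(states[train])) < 2 || length(unique(states[!train])) < 2)
    stop("single-class train or test split; use a different seed")

  rf <- randomForest::randomForest(feat[train, , drop = FALSE], states[train],
                                   ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(rf)
  importance <- data.frame(feature = rownames(imp),
                           mda = imp[, "MeanDecreaseAccuracy"],
                           mdg = imp[, "MeanDecreaseGini"],
                           row.names = NULL)
  importance$rank_mda <- rank(-importance$mda, ties.method = "first")
  importance$rank_mdg <- rank(-importance$mdg, ties.method = "first")

  pos <- levels(states)[2]
  scores <- stats::predict(rf, feat[!train, , drop = FALSE],
                           type = "prob")[, pos]
  truth <- states[!train] == pos
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!truth] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[truth] >= t), numeric(1)))

  structure(list(importance = importance,
                 top_features = importance$feature[
                   order(importance$rank_mda)][seq_len(min(top_k, nrow(importance)))],
                 roc = roc, auc = rank_auc(scores, truth),
                 train_fraction = train_fraction, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("random forest: held-out AUC = %.3f; top feature (MDA) = %s\n",
              x$auc, x$top_features[1]))
  invisible(x)
}

#' All-subsets covariate screening on a working linear model
#'
#' Enumerates every covariate subset up to `max_size` (p <= 15), fits a
#' Gaussian working model on log1p-transformed counts, and reports adjusted
#' R^2; the best subset of each size is flagged.  Collinear subsets (aliased
#' coefficients) are flagged, not fatal.  The empty subset is included with
#' adjusted R^2 = 0.
#'
#' @param y Count response.
#' @param X Data frame or matrix of covariates.
#' @param max_size Largest subset size (default: all covariates).
#' @return Data frame: `subset` (comma-joined names), `size`, `adj_r2`,
#'   `collinear`, `best_of_size`.
#' @export
all_subsets <- function(y, X, max_size = ncol(X)) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p > 15) stop("all-subsets enumeration limited to 15 covariates")
  max_size <- min(max_size, p)
  ly <- log1p(y)
  rows <- list(data.frame(subset = "(none)", size = 0, adj_r2 = 0,
                          collinear = FALSE))
  for (k in seq_len(max_size)) {
    for (cols in utils::combn(names(X), k, simplify = FALSE)) {
      fit <- stats::lm(ly ~ ., data = X[, cols, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        subset = paste(cols, collapse = ","), size = k,
        adj_r2 = summary(fit)$adj.r.squared,
        collinear = anyNA(stats::coef(fit)))
    }
  }
  out <- do.call(rbind, rows)
  out$best_of_size <- FALSE
  for (k in unique(out$size)) {
    i <- which(out$size == k)
    out$best_of_size[i[which.max(out$adj_r2[i])]] <- TRUE
  }
  out
}

negbin_irls <- function(y, X, max_iter = 15, tol = 1e-8, theta_max = 1e8) {
  n <- length(y); p <- ncol(X)
  beta <- tryCatch(qr.solve(X, log(pmax(y, 0.5))),
                   error = function(e) stop("singular design matrix"))
  eta <- drop(X %*% beta)
  theta <- 10
  for (outer in seq_len(max_iter)) {
    for (inner in seq_len(50)) {
      mu <- pmin(exp(eta), 1e10)
      w <- sqrt(mu / (1 + mu / theta))
      z <- eta + (y - mu) / mu
      fit <- stats::.lm.fit(X * w, z * w)
      if (fit$rank < p) stop("IRLS failed: rank-deficient weighted design")
      beta_new <- numeric(p)
      beta_new[fit$pivot] <- fit$coefficients
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      eta <- drop(X %*% beta)
      if (delta < tol) break
    }
    mu <- pmin(exp(eta), 1e10)
    # moment (Pearson chi-square) estimate of theta at the current mean
    chisq <- function(th) sum((y - mu)^2 / (mu + mu^2 / th)) - (n - p)
    theta_new <- if (chisq(theta_max) <= 0) theta_max else
      stats::uniroot(chisq, c(1e-4, theta_max), tol = 1e-6)$root
    if (abs(log(theta_new) - log(theta)) < 1e-6) {theta <- theta_new; break}
    theta <- theta_new
  }
  mu <- exp(eta)
  W <- mu / (1 + mu / theta)
  XtWX <- crossprod(X * sqrt(W))
  list(coefficients = beta, theta = theta, fitted = mu,
       vcov = tryCatch(solve(XtWX), error = function(e) matrix(NA, p, p)))
}

#' Negative-binomial regression with bootstrap significance
#'
#' Log-link negative-binomial (NB2) fit by iteratively reweighted least
#' squares with the dispersion estimated from the Pearson chi-square moment
#' equation, alternating to convergence.  Term significance uses a
#' case-resampling bootstrap of the coefficient estimates: two-sided
#' p = 2 * min{#(beta* <= 0), #(beta* >= 0)} + 1) / (n_bootstrap + 1),
#' with percentile 95% intervals.
#'
#' @param y Count response (not all zero).
#' @param X Data frame or matrix of covariates (n >= p + 2).
#' @param n_bootstrap Bootstrap resamples (faithful default 9,999;
#'   999 is adequate for screening).
#' @param seed Integer seed.
#' @return Object of class `negbin_glm_report`: `coefficients` (data frame
#'   `term`, `estimate`, `lower`, `upper`, `p_boot`), `theta`, `dispersion`
#'   (= 1/theta), `n_bootstrap`.
#' @export
negbin_glm <- function(y, X, n_bootstrap = 9999, seed = 1) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n < ncol(X) + 2) stop("need n >= p + 2 observations")
  if (all(y == 0)) stop("response is all zero")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  fit <- negbin_irls(y, Xm)
  set.seed(seed)
  boot <- matrix(NA_real_, n_bootstrap, ncol(Xm))
  b <- 1
  tries <- 0
  while (b <= n_bootstrap) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(negbin_irls(y[idx], Xm[idx, , drop = FALSE])$coefficients,
                    error = function(e) NULL)
    tries <- tries + 1
    if (tries > 2 * n_bootstrap + 100)
      stop("bootstrap refits failing repeatedly; check the design")
    if (is.null(est)) next
    boot[b, ] <- est
    b <- b + 1
  }
  p_boot <- vapply(seq_len(ncol(Xm)), function(j) {
    lo <- sum(boot[, j] <= 0); hi <- sum(boot[, j] >= 0)
    min(1, 2 * (min(lo, hi) + 1) / (n_bootstrap + 1))
  }, numeric(1))
  ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975)))
  structure(list(coefficients = data.frame(term = colnames(Xm),
                                           estimate = unname(fit$coefficients),
                                           lower = unname(ci[, 1]),
                                           upper = unname(ci[, 2]),
                                           p_boot = p_boot, row.names = NULL),
                 theta = fit$theta, dispersion = 1 / fit$theta,
                 n_bootstrap = n_bootstrap),
            class = "negbin_glm_report")
}

#' @export
print.negbin_glm_report <- function(x, ...) {
  cat(sprintf("negative-binomial GLM (dispersion %.3g, %d bootstraps)\n",
              x$dispersion, x$n_bootstrap))
  print(x$coefficients, digits = 3)
  invisible(x)
}
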