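wilson_interval <- function(p_hat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Fit the Sloan neutral community model
#'
#' Predicts each ASV's occurrence frequency from its mean relative abundance:
#' F_hat(p) = 1 - I_d(Nm*p, Nm*(1-p)), the upper tail of a beta distribution
#' at the detection limit d.  Nm is fitted by Levenberg-Marquardt nonlinear
#' least squares (coarse log-grid initialization), goodness of fit is the
#' frequency-space R^2 = 1 - SSE/SST, and each ASV is classed against the
#' Wilson 95% binomial sampling band of the prediction at n = number of
#' samples.
#'
#' @param table A [count_table] or ASV-by-sample count matrix.
#' @param detection_limit Detection limit d; default 1/mean(library size).
#' @param conf Confidence level of the occupancy band.
#' @return Object of class `ncm_fit`: `Nm`, `detection_limit`, `R2`,
#'   `n_samples`, and `asv` (data frame with mean relative abundance `p`,
#'   observed frequency `f`, predicted `f_hat`, band bounds, and
#'   `band` in above/within/below).
#' @export
fit_ncm <- function(table, detection_limit = NULL, conf = 0.95) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  n_samples <- ncol(x)
  if (n_samples < 10)
    warning("fewer than 10 samples: the occupancy fit will be unstable")
  totals <- colSums(x)
  if (is.null(detection_limit)) detection_limit <- 1 / mean(totals)
  d <- detection_limit
  rel <- sweep(x, 2, ifelse(totals > 0, totals, 1), "/")
  p_bar <- rowMeans(rel)
  f_obs <- rowMeans(x > 0)
  keep <- p_bar > 0
  p_bar <- p_bar[keep]; f_obs <- f_obs[keep]
  if (all(f_obs %in% c(0, 1)))
    stop("degenerate fit: every ASV occupancy is 0 or 1")

  pred <- function(Nm, p) stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
  sse <- function(Nm) sum((f_obs - pred(Nm, p_bar))^2)
  grid <- 10^seq(0, 5, by = 0.25)
  Nm0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(f_obs ~ pbeta(d, Nm * p_bar, Nm * (1 - p_bar),
                                    lower.tail = FALSE),
                      start = list(Nm = Nm0), lower = 1e-3,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("NCM fit diverged (last grid iterate Nm = ",
                             signif(Nm0, 4), "): ", conditionMessage(e)))
  Nm <- stats::coef(fit)[["Nm"]]
  f_hat <- pred(Nm, p_bar)
  R2 <- 1 - sum((f_obs - f_hat)^2) / sum((f_obs - mean(f_obs))^2)
  band <- wilson_interval(f_hat, n_samples, conf)
  cls <- ifelse(f_obs > band[, "upper"], "above",
                ifelse(f_obs < band[, "lower"], "below", "within"))
  structure(list(Nm = Nm, detection_limit = d, R2 = R2, n_samples = n_samples,
                 asv = data.frame(asv_id = names(p_bar), p = p_bar, f = f_obs,
                                  f_hat = f_hat, lower = band[, "lower"],
                                  upper = band[, "upper"], band = cls,
                                  row.names = NULL)),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: Nm = %.1f, R2 = %.3f (d = %.3g, %d samples)\n",
              x$Nm, x$R2, x$detection_limit, x$n_samples))
  print(table(x$asv$band))
  invisible(x)
}

#' Levins niche breadth per ASV
#'
#' B_i = 1 / sum_j (n_ij / N_i)^2: the effective number of samples an ASV
#' occupies (1 = confined to one sample, number of samples = perfectly even).
#' Zero-total ASVs are omitted with a warning.
#'
#' @param table A [count_table] or ASV-by-sample matrix.
#' @return Named numeric vector of B values.
#' @export
levins_niche <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  totals <- rowSums(x)
  if (any(totals == 0)) {
    warning("omitting zero-total ASV(s): ",
            paste(rownames(x)[totals == 0], collapse = ", "))
    x <- x[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  props <- x / totals
  1 / rowSums(props^2)
}

#' Classify ASVs as generalist / specialist / neutral by niche breadth
#'
#' Null distribution of each ASV's Levins B from fixed-marginal count
#' randomizations (vegan's `quasiswap_count` null model, preserving row and
#' column totals).  B above the null 97.5th percentile is a generalist,
#' below the 2.5th a specialist, otherwise neutral; degenerate nulls
#' (sd = 0) are flagged and classed neutral.
#'
#' @param table A [count_table] or count matrix.
#' @param n_null Number of null tables (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level of the null envelope.
#' @return Data frame of class `niche_result`: `asv_id`, `B`, `lower`,
#'   `upper`, `class`, `degenerate`.
#' @export
classify_niche <- function(table, n_null = 1000, seed = 1, conf = 0.95) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  stopifnot(n_null >= 100)
  keep <- rowSums(x) > 0
  x <- x[keep, , drop = FALSE]
  B <- levins_niche(x)
  nm <- vegan::nullmodel(x, "quasiswap_count")
  sims <- stats::simulate(nm, nsim = n_null, seed = seed)
  nullB <- apply(sims, 3, function(m) {
    props <- m / rowSums(m)
    1 / rowSums(props^2)
  })
  a <- (1 - conf) / 2
  lower <- apply(nullB, 1, stats::quantile, probs = a)
  upper <- apply(nullB, 1, stats::quantile, probs = 1 - a)
  degen <- apply(nullB, 1, stats::sd) == 0
  cls <- ifelse(B > upper, "generalist", ifelse(B < lower, "specialist", "neutral"))
  cls[degen] <- "neutral"
  out <- data.frame(asv_id = rownames(x), B = B, lower = lower, upper = upper,
                    class = cls, degenerate = degen, row.names = NULL)
  class(out) <- c("niche_result", "data.frame")
  out
}

#' Observed C-score of a presence-absence matrix
#'
#' Mean number of checkerboard units over species pairs:
#' CU_ij = (r_i - S_ij)(r_j - S_ij) with r the row totals and S the shared
#' site counts (Stone & Roberts).
#'
#' @param presence Binary species-by-site matrix (>= 2 rows).
#' @return The observed C-score (single number).
#' @export
c_score <- function(presence) {
  m <- as.matrix(presence)
  if (nrow(m) < 2) stop("need at least 2 species rows")
  m <- (m > 0) * 1
  r <- rowSums(m)
  S <- m %*% t(m)
  cu <- (r - S) * t(r - t(S)) # (r_i - S_ij)(r_j - S_ij)
  mean(cu[upper.tri(cu)])
}

#' C-score standardized effect size under the sequential-swap null
#'
#' Null matrices preserve both row and column totals exactly via sequential
#' 2x2 checkerboard swaps (vegan's compiled `"swap"` engine) after a burn-in,
#' thinned between saved matrices.  SES = (obs - mean_null)/sd_null; positive
#' SES indicates segregated co-occurrence, negative aggregated.  The
#' two-sided empirical p doubles the smaller tail,
#' p = 2 * min{(1 + #{null >= obs}), (1 + #{null <= obs})} / (1 + n_null),
#' capped at 1.
#'
#' @param presence Binary species-by-site matrix.
#' @param n_null Number of null matrices.
#' @param burn_in Swaps discarded before sampling.
#' @param thin Swaps between saved matrices.
#' @param seed Integer seed.
#' @return Object of class `cscore_result`: `observed`, `null_mean`,
#'   `null_sd`, `SES`, `p`, `n_null`.
#' @export
c_score_ses <- function(presence, n_null = 1000, burn_in = 5000, thin = 100,
                        seed = 1) {
  m <- (as.matrix(presence) > 0) * 1
  if (nrow(m) < 2) stop("need at least 2 species rows")
  obs <- c_score(m)
  nm <- vegan::nullmodel(m, "swap")
  sims <- tryCatch(
    stats::simulate(nm, nsim = n_null, burnin = burn_in, thin = thin,
                    seed = seed),
    error = function(e)
      stop("degenerate matrix: sequential swap cannot move it (",
           conditionMessage(e), ")"))
  null_scores <- apply(sims, 3, c_score)
  sd_null <- stats::sd(null_scores)
  if (sd_null == 0)
    stop("degenerate matrix: sequential swap cannot move it (no checkerboard submatrix)")
  ses <- (obs - mean(null_scores)) / sd_null
  ge <- (1 + sum(null_scores >= obs)) / (1 + n_null)
  le <- (1 + sum(null_scores <= obs)) / (1 + n_null)
  structure(list(observed = obs, null_mean = mean(null_scores),
                 null_sd = sd_null, SES = ses, p = min(1, 2 * min(ge, le)),
                 n_null = n_null),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, ...) {
  cat(sprintf("C-score %.4f vs null %.4f (sd %.4f): SES = %.2f, p = %.4g [%d nulls]\n",
              x$observed, x$null_mean, x$null_sd, x$SES, x$p, x$n_null))
  invisible(x)
}
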