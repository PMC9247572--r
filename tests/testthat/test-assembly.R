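test_that("NCM prediction is monotone and the fit recovers the simulated Nm", {
  cfg <- simulation_config(n_subjects = 25, n_asvs = 300, migration_Nm = 500,
                           seed = 42)
  ds <- simulate_neutral_community(cfg)
  fit <- fit_ncm(ds$table)
  expect_gt(fit$Nm, 500 * 0.75)
  expect_lt(fit$Nm, 500 * 1.25)
  expect_gte(fit$R2, 0.7)
  # predicted frequency increases with mean abundance at fixed Nm
  ord <- order(fit$asv$p)
  expect_true(all(diff(fit$asv$f_hat[ord]) >= -1e-12))
  expect_true(all(fit$asv$band %in% c("above", "within", "below")))
  expect_true(all(fit$asv$f_hat >= 0 & fit$asv$f_hat <= 1))
})

test_that("large Nm keeps occupancies near the prediction band", {
  # pointwise 95% occupancy bands under-cover somewhat because each ASV's
  # mean abundance is itself estimated; the bulk of ASVs stays within
  cfg <- simulation_config(n_subjects = 25, n_asvs = 150, migration_Nm = 1e5,
                           seed = 13)
  ds <- simulate_neutral_community(cfg)
  fit <- fit_ncm(ds$table)
  expect_gt(mean(fit$asv$band == "within"), 0.75)
  expect_gt(fit$R2, 0.85)
})

test_that("deterministic occupancy degrades the neutral fit", {
  cfg <- simulation_config(n_subjects = 25, n_asvs = 200, migration_Nm = 500,
                           seed = 21)
  ds <- simulate_neutral_community(cfg)
  neutral_R2 <- fit_ncm(ds$table)$R2
  # force half the ASVs deterministic: present iff abundance above their median
  x <- ds$table$counts
  half <- seq_len(100)
  for (i in half) {
    med <- stats::median(x[i, ])
    x[i, x[i, ] <= med] <- 0
  }
  forced_R2 <- fit_ncm(x)$R2
  expect_lt(forced_R2, neutral_R2)
})

test_that("Levins niche breadth matches closed forms", {
  x <- rbind(uniform = rep(7, 5), single = c(9, 0, 0, 0, 0),
             half = c(4, 4, 0, 0, 0))
  colnames(x) <- sprintf("s%d", 1:5)
  B <- levins_niche(x)
  expect_equal(unname(B), c(5, 1, 2))
  x0 <- rbind(x, zero = rep(0, 5))
  expect_warning(B0 <- levins_niche(x0), "zero-total")
  expect_length(B0, 3)
})

test_that("niche classification flags constructed generalists and specialists", {
  set.seed(2)
  # patchy background: most ASVs concentrated in few samples
  x <- matrix(rnbinom(30 * 12, mu = 5, size = 0.15), 30, 12)
  x[1, ] <- 40                     # perfectly even -> generalist
  x[2, ] <- c(480, rep(0, 11))     # one sample -> specialist
  x <- x[rowSums(x) > 0, ]
  dimnames(x) <- list(sprintf("ASV%d", seq_len(nrow(x))),
                      sprintf("s%d", 1:12))
  res <- classify_niche(x, n_null = 300, seed = 4)
  expect_equal(res$class[res$asv_id == "ASV1"], "generalist")
  expect_equal(res$class[res$asv_id == "ASV2"], "specialist")
  expect_equal(nrow(res), nrow(x))
})

test_that("niche classes are mostly neutral on a structureless table", {
  set.seed(5)
  # exchangeable allocation: each ASV total spread multinomially over
  # samples, matching the fixed-marginal null's dispersion (cell-wise
  # overdispersed draws would rightly be classed specialists)
  totals <- rnbinom(60, mu = 150, size = 1) + 20
  x <- t(vapply(totals, function(N) rmultinom(1, N, rep(1 / 20, 20))[, 1],
                numeric(20)))
  dimnames(x) <- list(sprintf("ASV%d", 1:60), sprintf("s%d", 1:20))
  res <- classify_niche(x, n_null = 300, seed = 6)
  expect_gt(mean(res$class == "neutral"), 0.85)
})

test_that("C-score matches hand enumeration", {
  expect_equal(c_score(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(c_score(matrix(1, 2, 2)), 0)
  m <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 1, 0, 1))
  # brute-force pair enumeration oracle
  pairs <- utils::combn(nrow(m), 2)
  cu <- apply(pairs, 2, function(ij) {
    ri <- sum(m[ij[1], ]); rj <- sum(m[ij[2], ])
    s <- sum(m[ij[1], ] & m[ij[2], ])
    (ri - s) * (rj - s)
  })
  expect_equal(c_score(m), mean(cu))
  expect_error(c_score(m[1, , drop = FALSE]), "2 species")
})

test_that("sequential-swap nulls preserve marginals and detect segregation", {
  set.seed(3)
  m <- matrix(rbinom(15 * 12, 1, 0.4), 15, 12)
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  nm <- vegan::nullmodel(m, "swap")
  sims <- stats::simulate(nm, nsim = 50, burnin = 1000, thin = 50, seed = 9)
  for (k in c(1, 25, 50)) {
    expect_equal(rowSums(sims[, , k]), rowSums(m), ignore_attr = TRUE)
    expect_equal(colSums(sims[, , k]), colSums(m), ignore_attr = TRUE)
  }
  seg <- matrix(0, 10, 10)
  seg[1:5, 1:5] <- 1
  seg[6:10, 6:10] <- 1
  r <- c_score_ses(seg, n_null = 300, burn_in = 2000, thin = 50, seed = 1)
  expect_gt(r$SES, 2)
  expect_lt(r$p, 0.05)
  expect_error(c_score_ses(matrix(1, 3, 3)), "degenerate")
})
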