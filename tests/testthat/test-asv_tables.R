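test_that("count tables round-trip through TSV with taxonomy intact", {
  cfg <- simulation_config(n_subjects = 4, n_asvs = 20, seed = 3)
  ds <- simulate_paired_cohort(cfg)
  tmp <- file.path(tempdir(), "rt_counts.tsv")
  tmpm <- file.path(tempdir(), "rt_meta.tsv")
  write_count_table(ds$table, tmp, tmpm)
  back <- read_count_table(tmp, tmpm)
  expect_identical(back$counts, ds$table$counts)
  expect_identical(back$metadata$state, ds$table$metadata$state)

  ex <- read_count_table(
    system.file("extdata", "example_counts.tsv", package = "microdrivers"),
    system.file("extdata", "example_metadata.tsv", package = "microdrivers"))
  expect_length(ex$taxonomy, 6)
  expect_match(ex$taxonomy[["ASV2"]], "g__Oscillospira")
  expect_equal(unname(ex$counts["ASV4", "S03_BT"]), 410)
})

test_that("metadata must cover every sample and ids must be unique", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2"), state = "BT")
  expect_error(count_table(m, meta), "s3")
  m2 <- m; rownames(m2) <- c("a", "a")
  expect_error(count_table(m2, rbind(meta, data.frame(sample_id = "s3", state = "AT"))),
               "duplicate")
  m3 <- m; m3[1, 1] <- -1
  expect_error(toy_table(m3), "non-negative")
})

test_that("filter keeps exactly the ASVs satisfying the prevalence/abundance rule", {
  # 5 ASVs x 10 samples: ASV1-2 prevalent and abundant, ASV3 rare+scarce,
  # ASV4 rare+scarce, ASV5 rare+scarce
  counts <- rbind(
    ASV1 = rep(50, 10),                      # prevalent, abundant
    ASV2 = c(rep(80, 5), rep(20, 5)),        # prevalent, abundant
    ASV3 = c(1, rep(0, 9)),                  # 10% prevalence, tiny
    ASV4 = c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # 10% prevalence, tiny
    ASV5 = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))  # 10% prevalence, tiny
  colnames(counts) <- sprintf("s%d", 1:10)
  tab <- toy_table(counts)
  for (rule in c("or", "and")) {
    kept <- suppressMessages(filter_asvs(tab, 0.20, 0.025, rule = rule))
    expect_setequal(rownames(kept$counts), c("ASV1", "ASV2"))
  }
  expect_identical(filter_asvs(tab, 0, 0)$counts, tab$counts)
  # idempotence
  once <- suppressMessages(filter_asvs(tab))
  twice <- suppressMessages(filter_asvs(once))
  expect_identical(once$counts, twice$counts)
})

test_that("relative abundance columns sum to one and match arithmetic", {
  tab <- toy_table(matrix(c(2, 2, 1, 1, 2, 3), 3, 2))
  rel <- to_relative(tab)
  expect_equal(unname(rel$proportions[, 1]), c(0.4, 0.4, 0.2))
  expect_equal(unname(rel$proportions[, 2]), c(1/6, 1/3, 1/2))
  expect_equal(unname(colSums(rel$proportions)), c(1, 1))
  tab0 <- toy_table(cbind(c(1, 2, 3), c(0, 0, 0)))
  expect_warning(rel0 <- to_relative(tab0), "all-zero")
  expect_equal(unname(rel0$proportions[, 2]), c(0, 0, 0))
})

test_that("TMM factors are 1 for identical or depth-scaled columns", {
  x <- matrix(rpois(40, 50) + 1, 10, 4)
  tab <- toy_table(cbind(x[, 1], x[, 1], x[, 1], x[, 1]))
  expect_equal(unname(tmm_normalize(tab)$norm_factors), rep(1, 4))
  tab2 <- toy_table(cbind(A = x[, 1], B = 2 * x[, 1]))
  nf <- tmm_normalize(tab2)$norm_factors
  expect_equal(unname(nf), c(1, 1))
  expect_equal(exp(mean(log(tmm_normalize(toy_table(x))$norm_factors))), 1,
               tolerance = 1e-6)
})

test_that("TMM matches an independent M/A trimmed weighted mean", {
  # sample B = sample A with one ASV inflated 10x
  set.seed(4)
  a <- rpois(50, 200) + 50
  b <- a; b[7] <- a[7] * 10
  tab <- toy_table(cbind(A = a, B = b))
  nf <- tmm_normalize(tab)$norm_factors

  # oracle: direct trimmed precision-weighted mean of M values (B vs ref A)
  Na <- sum(a); Nb <- sum(b)
  M <- log2((b / Nb) / (a / Na))
  A <- 0.5 * log2((b / Nb) * (a / Na))
  w <- 1 / ((Nb - b) / (Nb * b) + (Na - a) / (Na * a))
  n <- length(M)
  loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f_b <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  oracle <- c(1, f_b) / exp(mean(log(c(1, f_b))))
  expect_equal(unname(nf), oracle, tolerance = 1e-10)
})
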