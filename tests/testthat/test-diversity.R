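test_that("alpha diversity matches closed forms", {
  tab <- toy_table(cbind(a = c(5, 5, 5, 5), b = c(9, 0, 0, 0),
                         d = c(1, 2, 3, 0)))
  a <- alpha_diversity(tab)
  expect_equal(a$richness, c(4, 1, 3))
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$shannon[2], 0)
  expect_equal(a$shannon[3],
               -sum(c(1, 2, 3) / 6 * log(c(1, 2, 3) / 6)), tolerance = 1e-12)
})

test_that("rarefaction expectation matches the hypergeometric form", {
  tab <- toy_table(matrix(c(5, 5), 2, 1))
  r <- rarefaction_curve(tab, c(1, 2, 10))
  expect_equal(r$expected_richness[1], 1) # one draw sees exactly one ASV
  expect_equal(r$expected_richness[2], 2 * (1 - choose(5, 2) / choose(10, 2)),
               tolerance = 1e-12) # = 1.5556
  expect_equal(r$expected_richness[3], 2) # full depth -> observed richness
  expect_warning(rarefaction_curve(tab, c(5, 50)), "clipped")
})

test_that("Bray-Curtis matches arithmetic and stays in [0,1]", {
  tab <- toy_table(cbind(a = c(2, 0, 1), b = c(1, 1, 0), d = c(2, 0, 1)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], 0.6)
  expect_equal(d["a", "d"], 0)
  disj <- toy_table(cbind(a = c(3, 0), b = c(0, 7)))
  expect_equal(as.matrix(bray_curtis(disj))["a", "b"], 1)
  x <- lognormal_counts(20, 10, seed = 2)
  dd <- bray_curtis(toy_table(x))
  expect_true(all(dd >= 0 & dd <= 1))
})

test_that("PCoA reproduces classical scaling geometry", {
  d2 <- stats::as.dist(matrix(c(0, 2, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  o <- pcoa(d2)
  expect_equal(ncol(o$coordinates), 1)
  expect_equal(sort(o$coordinates[, 1]), c(-1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # collinear points at d = (1,1,2)
  d3 <- stats::as.dist(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  o3 <- pcoa(d3)
  expect_equal(sort(o3$coordinates[, 1]), c(-1, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # known 2-D Euclidean configuration recovered up to rotation/reflection
  set.seed(6)
  conf <- matrix(rnorm(20), 10, 2)
  o10 <- pcoa(stats::dist(conf))
  pro <- vegan::procrustes(conf, o10$coordinates[, 1:2], symmetric = FALSE)
  expect_lt(max(abs(pro$Yrot + matrix(pro$translation, 10, 2, byrow = TRUE) - conf)),
            1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("NMDS embeds embeddable configurations at low stress, reproducibly", {
  set.seed(8)
  conf <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  rownames(conf) <- sprintf("s%d", 1:20)
  d <- stats::dist(conf)
  o <- nmds(d, k = 2, restarts = 5, seed = 4)
  expect_lt(o$stress, 0.01)
  o2 <- nmds(d, k = 2, restarts = 5, seed = 4)
  expect_identical(o$coordinates, o2$coordinates)
})

test_that("PERMANOVA separates real clusters and respects the null", {
  set.seed(10)
  x <- cbind(matrix(rlnorm(300, 2), 30, 10),
             matrix(rlnorm(300, 4.5), 30, 10))
  colnames(x) <- sprintf("s%d", 1:20)
  rownames(x) <- sprintf("ASV%d", 1:30)
  d <- bray_curtis(x)
  groups <- rep(c("A", "B"), each = 10)
  r <- permanova(d, groups, n_permutations = 199, seed = 1)
  expect_equal(r$p, 1 / 200)
  expect_gt(r$R2, 0.2)
  expect_error(permanova(d, rep("A", 20)), "2 groups")
  # identical groups -> F near 1 on average
  fs <- vapply(1:30, function(s) {
    set.seed(s)
    xx <- matrix(rlnorm(200, 2), 10, 20, dimnames = list(NULL, sprintf("s%d", 1:20)))
    permanova(bray_curtis(xx), sample(groups), n_permutations = 49, seed = s)$pseudo_F
  }, numeric(1))
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)
})

test_that("rank-sum differential matches exact enumeration and flags planted shifts", {
  # groups {1,2} vs {3,4}: U = 0, exact two-sided p = 1/3
  x <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("ASV1", sprintf("s%d", 1:4)))
  d <- rank_sum_differential(x, c("g1", "g1", "g2", "g2"))
  expect_equal(d$statistic, 0)
  expect_equal(d$p, 1 / 3, tolerance = 1e-12)
  # identical groups -> p 1 for constant rows
  xc <- matrix(5, 3, 6, dimnames = list(sprintf("A%d", 1:3), sprintf("s%d", 1:6)))
  dc <- rank_sum_differential(xc, rep(c("a", "b"), 3))
  expect_true(all(dc$p == 1))
})
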