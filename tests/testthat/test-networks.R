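test_that("SparCC output is a valid correlation matrix and recovers plants", {
  set.seed(7)
  n <- 60; p <- 20
  z <- matrix(rnorm(p * n), p, n)
  z[2, ] <- 0.9 * z[1, ] + sqrt(1 - 0.81) * rnorm(n)
  abun <- exp(1.5 * z + 3)
  counts <- vapply(seq_len(n), function(j)
    rmultinom(1, 2e4, abun[, j] / sum(abun[, j]))[, 1], numeric(p))
  rownames(counts) <- sprintf("ASV%d", 1:p)
  colnames(counts) <- sprintf("s%d", 1:n)
  rho <- sparcc(counts, seed = 1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, p))
  expect_true(all(abs(rho) <= 1))
  expect_gt(rho["ASV1", "ASV2"], 0.6)
  expect_error(sparcc(counts[1:3, ]), "at least 4")
})

test_that("edge significance is minimal for planted pairs and valid overall", {
  set.seed(8)
  n <- 60; p <- 20
  z <- matrix(rnorm(p * n), p, n)
  z[2, ] <- 0.9 * z[1, ] + sqrt(1 - 0.81) * rnorm(n)
  abun <- exp(1.5 * z + 3)
  counts <- vapply(seq_len(n), function(j)
    rmultinom(1, 2e4, abun[, j] / sum(abun[, j]))[, 1], numeric(p))
  rownames(counts) <- sprintf("ASV%d", 1:p)
  rho <- sparcc(counts, n_iterations = 10, seed = 2)
  pm <- edge_significance(counts, rho, n_bootstraps = 40, seed = 3,
                          n_iterations = 5)
  expect_equal(pm["ASV1", "ASV2"], 1 / 41)
  off <- pm[upper.tri(pm)]
  expect_true(all(off > 0 & off <= 1))
})

test_that("network building applies the strict inclusion rule", {
  ids <- sprintf("A%d", 1:4)
  rho <- matrix(0, 4, 4, dimnames = list(ids, ids))
  rho[1, 2] <- rho[2, 1] <- 0.8
  rho[1, 3] <- rho[3, 1] <- 0.3    # exactly at threshold: excluded
  rho[2, 4] <- rho[4, 2] <- -0.5   # negative, |rho| mode keeps it
  diag(rho) <- 1
  p <- matrix(0.01, 4, 4)
  net <- build_network(rho, p)
  expect_equal(igraph::gsize(net$graph), 2)
  expect_setequal(igraph::V(net$graph)$name, c("A1", "A2", "A4"))
  signed <- suppressMessages(build_network(rho, p, use_absolute = FALSE))
  expect_equal(igraph::gsize(signed$graph), 1)
  expect_warning(empty <- build_network(diag(4), p), "empty")
  expect_equal(igraph::gorder(empty$graph), 0)
  # edge count monotone in thresholds
  full <- matrix(runif(16, -1, 1), 4, 4, dimnames = list(ids, ids))
  full <- (full + t(full)) / 2; diag(full) <- 1
  pmat <- matrix(runif(16), 4, 4); pmat <- (pmat + t(pmat)) / 2
  e1 <- igraph::gsize(suppressWarnings(build_network(full, pmat, 0.1, 0.5))$graph)
  e2 <- igraph::gsize(suppressWarnings(build_network(full, pmat, 0.4, 0.5))$graph)
  e3 <- igraph::gsize(suppressWarnings(build_network(full, pmat, 0.1, 0.2))$graph)
  expect_lte(e2, e1)
  expect_lte(e3, e1)
})

test_that("greedy modularity finds planted blocks and exact toy partitions", {
  ids <- sprintf("A%d", 1:6)
  rho <- matrix(0, 6, 6, dimnames = list(ids, ids))
  tri <- function(i) t(utils::combn(i, 2))
  for (e in 1:3) {
    rho[tri(1:3)[e, 1], tri(1:3)[e, 2]] <- 0.9
    rho[tri(4:6)[e, 1], tri(4:6)[e, 2]] <- 0.9
  }
  rho <- rho + t(rho); diag(rho) <- 1
  net <- detect_modules(build_network(rho, matrix(0.001, 6, 6)))
  expect_equal(length(unique(net$modules$module)), 2)
  expect_equal(attr(net$modules, "Q"), 0.5)
  # complete graph: a single module
  k4 <- matrix(0.9, 4, 4, dimnames = list(ids[1:4], ids[1:4])); diag(k4) <- 1
  netk4 <- detect_modules(build_network(k4, matrix(0.001, 4, 4)))
  expect_equal(length(unique(netk4$modules$module)), 1)
  # planted 3-block recovery
  set.seed(12)
  n <- 30
  truth <- rep(1:3, each = 10)
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- rbinom(1, 1, ifelse(truth[i] == truth[j], 0.8, 0.05))
  ids30 <- sprintf("A%d", 1:n)
  dimnames(adj) <- list(ids30, ids30)
  rho30 <- adj * 0.9
  rho30 <- rho30 + t(rho30); diag(rho30) <- 1
  net30 <- detect_modules(build_network(rho30, matrix(0.001, n, n)))
  found <- net30$modules$module[match(ids30, net30$modules$asv_id)]
  expect_gte(rand_index(truth[!is.na(found)], found[!is.na(found)]), 0.95)
})

test_that("module labels are invariant under node relabeling", {
  set.seed(14)
  n <- 18
  truth <- rep(1:2, each = 9)
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- rbinom(1, 1, ifelse(truth[i] == truth[j], 0.7, 0.05))
  rho <- (adj + t(adj)) * 0.8; diag(rho) <- 1
  ids <- sprintf("A%d", 1:n)
  dimnames(rho) <- list(ids, ids)
  net1 <- detect_modules(build_network(rho, matrix(0.001, n, n)))
  perm <- sample(n)
  rho2 <- rho[perm, perm]
  net2 <- detect_modules(build_network(rho2, matrix(0.001, n, n)))
  m1 <- net1$modules$module[match(ids, net1$modules$asv_id)]
  m2 <- net2$modules$module[match(ids, net2$modules$asv_id)]
  keep <- !is.na(m1) & !is.na(m2)
  expect_equal(rand_index(m1[keep], m2[keep]), 1)
})

test_that("network metrics match closed forms on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- sprintf("A%d", 1:4)
  m <- network_metrics(k4)
  expect_equal(m$ave_degree, 3)
  expect_equal(m$density, 1)
  expect_equal(m$ave_path_length, 1)
  path3 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  mb <- igraph::betweenness(path3, normalized = TRUE)
  expect_equal(unname(mb["B"]), 1)
  expect_error(network_metrics(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("common subnetwork tags edges by provenance", {
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")), directed = FALSE)
  cs_same <- common_subnetwork(g1, g1)
  expect_true(all(cs_same$edges$tag == "both"))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "d"), to = c("e", "e")), directed = FALSE)
  cs_disj <- common_subnetwork(g1, g2)
  expect_setequal(unique(cs_disj$edges$tag), c("BT-only", "AT-only"))
  g3 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")), directed = FALSE)
  cs <- common_subnetwork(g1, g3)
  expect_equal(sort(table(cs$edges$tag), decreasing = TRUE),
               sort(table(c("both", "both", "BT-only")), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("indicator values match the specificity x fidelity definition", {
  x <- rbind(
    bt_only = c(1, 1, 1, 0, 0, 0),   # all BT, absent AT
    even    = c(2, 2, 2, 2, 2, 2))   # same everywhere
  colnames(x) <- sprintf("s%d", 1:6)
  states <- rep(c("BT", "AT"), each = 3)
  # pass abundances directly: per-sample renormalization would couple the
  # two rows compositionally and distort the specificity of the even ASV
  res <- indicator_species(x, states, n_permutations = 500, seed = 1)
  r1 <- res[res$asv_id == "bt_only" & res$state == "BT", ]
  expect_equal(r1$indval, 1)
  expect_lt(r1$p, 0.05)
  expect_equal(res$indval[res$asv_id == "even"], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("indicator significance is calibrated on shuffled labels", {
  set.seed(20)
  x <- lognormal_counts(40, 30, seed = 20)
  states <- sample(rep(c("BT", "AT"), 15))
  res <- indicator_species(x, states, n_permutations = 200, seed = 2)
  expect_lt(mean(res$p < 0.05), 0.15)
})
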