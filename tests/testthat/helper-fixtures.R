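# Small builders shared across test files.

toy_table <- function(counts, states = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("ASV%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (is.null(states)) states <- rep(c("BT", "AT"), length.out = ncol(counts))
  meta <- data.frame(sample_id = colnames(counts), state = states,
                     subject = colnames(counts))
  count_table(counts, meta)
}

# a pair of star graphs around node "X" with prescribed neighbor counts
star_pair <- function(n_bt, n_at, exclusive) {
  sh <- n_at - exclusive
  shared <- if (sh > 0) sprintf("S%d", seq_len(sh)) else character(0)
  bt_only <- if (n_bt - sh > 0) sprintf("B%d", seq_len(n_bt - sh)) else character(0)
  at_only <- if (exclusive > 0) sprintf("E%d", seq_len(exclusive)) else character(0)
  g_bt <- igraph::graph_from_data_frame(
    data.frame(from = "X", to = c(shared, bt_only)), directed = FALSE)
  g_at <- igraph::graph_from_data_frame(
    data.frame(from = "X", to = c(shared, at_only)), directed = FALSE)
  list(bt = g_bt, at = g_at)
}

# independent lognormal multinomial counts (no correlation structure)
lognormal_counts <- function(p, n, depth = 2e4, sdlog = 1.5, seed = 1) {
  set.seed(seed)
  abun <- matrix(stats::rlnorm(p * n, 3, sdlog), p, n)
  counts <- vapply(seq_len(n), function(j)
    stats::rmultinom(1, depth, abun[, j] / sum(abun[, j]))[, 1], numeric(p))
  dimnames(counts) <- list(sprintf("ASV%d", seq_len(p)),
                           sprintf("s%d", seq_len(n)))
  counts
}

# adjusted-for-chance-free Rand index of two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

driver_counts_path <- function() {
  system.file("extdata", "driver_node_counts.tsv", package = "microdrivers")
}

pipeline_fixture_config <- function(seed = 101) {
  # paired cohort with one rewiring (driver) plant: ASV2 sits in a small BT
  # module and a larger AT module; module members get solid abundance
  set.seed(1)
  p <- 150
  w <- stats::rlnorm(p, 0, 2)
  mod_bt <- c(2, 10, 11, 12)
  mod_at <- c(2, 20:32) # a large AT module: the driver's rewiring must
                        # stand out of the noise-edge background at n = 25
  w[union(mod_bt, mod_at)] <- stats::quantile(w, 0.9)
  cfg <- simulation_config(
    n_subjects = 25, n_asvs = p, source_community = w / sum(w),
    planted_modules = list(list(asvs = mod_bt, r = 0.9, state = "BT"),
                           list(asvs = mod_at, r = 0.9, state = "AT")),
    seed = seed)
  pipeline_config(sim_config = cfg, n_permutations = 99,
                  sparcc_iterations = 8, sparcc_bootstraps = 20,
                  cscore_nulls = 200, run_niche = FALSE,
                  glm_bootstraps = 99, rf_trees = 300, seed = seed)
}
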