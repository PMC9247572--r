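sparcc_basis <- function(T_mat, excluded) {
  # Solve M w = t for basis variances under the sparsity approximation,
  # with excluded pairs removed from the system (Friedman & Alm).
  p <- nrow(T_mat)
  M <- matrix(1, p, p)
  diag(M) <- p - 2
  t_vec <- rowSums(T_mat)
  if (length(excluded) > 0) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1]; j <- excluded[k, 2]
      M[i, j] <- M[j, i] <- 0
      M[i, i] <- M[i, i] - 1
      M[j, j] <- M[j, j] - 1
      t_vec[i] <- t_vec[i] - T_mat[i, j]
      t_vec[j] <- t_vec[j] - T_mat[i, j]
    }
  }
  w <- tryCatch(solve(M, t_vec),
                error = function(e) stop("unsolvable basis-variance system after exclusions"))
  pmax(w, 1e-10)
}

sparcc_once <- function(frac, exclusion_threshold, n_exclusion_rounds) {
  p <- nrow(frac)
  logf <- log(frac)
  # T[i,j] = var(log(x_i/x_j)) = var(log x_i) + var(log x_j) - 2 cov
  V <- stats::cov(t(logf))
  v <- diag(V)
  T_mat <- outer(v, v, "+") - 2 * V
  excluded <- matrix(integer(0), 0, 2)
  repeat {
    w <- sparcc_basis(T_mat, excluded)
    rho <- (outer(w, w, "+") - T_mat) / (2 * sqrt(outer(w, w)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (nrow(excluded) >= n_exclusion_rounds) break
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded) > 0) {
      cand[excluded] <- 0
      cand[excluded[, 2:1, drop = FALSE]] <- 0
    }
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    # keep each variable in at least 2 equations
    degree_excluded <- tabulate(c(excluded), nbins = p)
    if (any(degree_excluded[ij] >= p - 3)) break
    excluded <- rbind(excluded, ij)
  }
  rho
}

#' SparCC compositional correlation matrix
#'
#' Iterative log-ratio variance estimate of basis correlations robust to
#' compositionality (Friedman & Alm): per iteration, fractions are
#' Dirichlet-resampled from counts (+1 pseudocount), the full log-ratio
#' variance matrix is reduced to basis variances under a sparsity
#' assumption, and strongly correlated pairs (|rho| above
#' `exclusion_threshold`) are iteratively excluded from the linear system.
#' The returned matrix is the element-wise median over iterations, clipped
#' to \[-1, 1\].
#'
#' @param table A [count_table] or ASV-by-sample count matrix (>= 4 ASVs).
#' @param n_iterations Outer Dirichlet-resampling iterations.
#' @param exclusion_threshold |rho| above which a pair is excluded.
#' @param n_exclusion_rounds Maximum excluded pairs per iteration.
#' @param seed Integer seed.
#' @return Symmetric ASV-by-ASV correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_iterations = 20, exclusion_threshold = 0.1,
                   n_exclusion_rounds = 10, seed = 1) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  p <- nrow(x)
  if (p < 4) stop("SparCC needs at least 4 ASVs")
  set.seed(seed)
  acc <- array(NA_real_, c(p, p, n_iterations))
  for (it in seq_len(n_iterations)) {
    frac <- apply(x + 1, 2, rdirichlet1)
    acc[, , it] <- sparcc_once(frac, exclusion_threshold, n_exclusion_rounds)
  }
  rho <- apply(acc, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}

#' Permutation significance of SparCC correlations
#'
#' Null correlation distributions from tables whose ASV rows are permuted
#' independently across samples (breaking all between-ASV association while
#' preserving marginals); two-sided
#' p = (1 + #{|rho_null| >= |rho_obs|}) / (1 + n_bootstraps), pooled over
#' all null matrices per pair.
#'
#' @param table A [count_table] or count matrix.
#' @param rho Observed SparCC correlation matrix.
#' @param n_bootstraps Number of null tables (>= 20).
#' @param seed Integer seed.
#' @param ... Passed to [sparcc()] for the null fits.
#' @return Matrix of pseudo p-values (diagonal = NA).
#' @export
edge_significance <- function(table, rho, n_bootstraps = 100, seed = 1, ...) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  stopifnot(n_bootstraps >= 20)
  set.seed(seed)
  exceed <- matrix(0, nrow(x), nrow(x))
  for (b in seq_len(n_bootstraps)) {
    perm <- t(apply(x, 1, sample))
    rownames(perm) <- rownames(x)
    colnames(perm) <- colnames(x)
    rho_null <- sparcc(perm, seed = sample.int(.Machine$integer.max, 1), ...)
    exceed <- exceed + (abs(rho_null) >= abs(rho))
  }
  p <- (1 + exceed) / (1 + n_bootstraps)
  diag(p) <- NA
  dimnames(p) <- dimnames(rho)
  p
}

#' Build a co-occurrence network from correlations and p-values
#'
#' Edges satisfy |rho| > `rho_min` (strict) and p < `alpha` (strict); with
#' `use_absolute = FALSE` only positive correlations above `rho_min` pass,
#' matching a signed reading of the inclusion rule.  Isolated nodes are
#' dropped.
#'
#' @param rho Symmetric correlation matrix.
#' @param p Matrix of edge p-values (same shape).
#' @param rho_min Correlation magnitude threshold.
#' @param alpha Significance threshold.
#' @param use_absolute Use |rho| (default) or signed rho for the threshold.
#' @return Object of class `co_network`: `graph` (igraph, edge attributes
#'   `weight` = rho, `sign`), `modules` (NULL until [detect_modules()]),
#'   `metrics` (see [network_metrics()]).
#' @export
build_network <- function(rho, p, rho_min = 0.3, alpha = 0.05,
                          use_absolute = TRUE) {
  stopifnot(all(dim(rho) == dim(p)))
  strength <- if (use_absolute) abs(rho) else rho
  if (!use_absolute)
    message("build_network: signed mode, only rho > ", rho_min, " retained")
  keep <- strength > rho_min & p < alpha & upper.tri(rho)
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rho)))
  if (nrow(idx) == 0) {
    warning("empty network: no edge passes the inclusion rule")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                        weight = rho[keep], sign = sign(rho[keep]))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  net <- structure(list(graph = g, modules = NULL, metrics = NULL),
                   class = "co_network")
  if (igraph::gorder(g) >= 2) net$metrics <- network_metrics(net)
  net
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges\n",
              igraph::gorder(x$graph), igraph::gsize(x$graph)))
  if (!is.null(x$modules))
    cat("  modules:", length(unique(x$modules$module)),
        sprintf("(Q = %.3f)\n", attr(x$modules, "Q")))
  invisible(x)
}

#' Detect modules by greedy modularity optimization
#'
#' Agglomerative greedy maximization of modularity (Clauset-Newman-Moore)
#' on absolute edge weights, via `igraph::cluster_fast_greedy`.
#'
#' @param net A `co_network` with at least one edge.
#' @param seed Integer seed (the algorithm is deterministic; kept for
#'   interface symmetry).
#' @return The network with `modules` filled: data frame `asv_id`, `module`,
#'   with attribute `Q` (modularity of the partition).
#' @export
detect_modules <- function(net, seed = 1) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  if (igraph::gsize(g) < 1) stop("module detection needs at least one edge")
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(g, weights = abs(igraph::E(g)$weight))
  membership <- as.integer(igraph::membership(cl))
  Q <- igraph::modularity(g, membership, weights = abs(igraph::E(g)$weight))
  if (Q <= 0) {
    # a partition no better than the trivial one: keep a single module
    membership <- rep(1L, igraph::gorder(g))
    Q <- 0
  }
  mod <- data.frame(asv_id = igraph::V(g)$name, module = membership,
                    row.names = NULL)
  attr(mod, "Q") <- Q
  net$modules <- mod
  net
}

#' Summary metrics of a co-occurrence network
#'
#' Node and edge counts, average degree 2E/N, density 2E/(N(N-1)), average
#' path length over connected pairs, and mean normalized node betweenness.
#'
#' @param net A `co_network` (or igraph) with >= 2 nodes.
#' @return Data frame with one row: `nodes`, `edges`, `ave_degree`,
#'   `ave_path_length`, `density`, `betweenness`.
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "co_network")) net$graph else net
  n <- igraph::gorder(g)
  if (n < 2) stop("metrics undefined for fewer than 2 nodes")
  e <- igraph::gsize(g)
  data.frame(nodes = n, edges = e,
             ave_degree = 2 * e / n,
             ave_path_length = igraph::mean_distance(g, directed = FALSE,
                                                     weights = NA),
             density = 2 * e / (n * (n - 1)),
             betweenness = mean(igraph::betweenness(g, normalized = TRUE,
                                                    weights = NA)))
}

#' Merge two networks into a provenance-tagged common subnetwork
#'
#' Union graph of the BT and AT networks with every edge tagged `"both"`,
#' `"BT-only"`, or `"AT-only"` (the green/red/blue semantics of a common
#' subnetwork plot).
#'
#' @param net_bt,net_at `co_network` objects (or igraphs).
#' @return List of class `common_subnetwork`: `edges` (data frame `from`,
#'   `to`, `tag`) and `graph` (igraph with edge attribute `tag`).
#' @export
common_subnetwork <- function(net_bt, net_at) {
  g1 <- if (inherits(net_bt, "co_network")) net_bt$graph else net_bt
  g2 <- if (inherits(net_at, "co_network")) net_at$graph else net_at
  key <- function(g) {
    if (igraph::gsize(g) == 0) return(character(0))
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  }
  k1 <- key(g1); k2 <- key(g2)
  all_keys <- union(k1, k2)
  tag <- ifelse(all_keys %in% k1 & all_keys %in% k2, "both",
                ifelse(all_keys %in% k1, "BT-only", "AT-only"))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      tag = tag, stringsAsFactors = FALSE)
  g <- if (nrow(edges) > 0) igraph::graph_from_data_frame(edges, directed = FALSE)
       else igraph::make_empty_graph(0, directed = FALSE)
  structure(list(edges = edges, graph = g), class = "common_subnetwork")
}

#' Write a network as a weighted edge-list TSV
#'
#' @param net A `co_network`.
#' @param path Destination TSV.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  el <- igraph::as_edgelist(g)
  out <- data.frame(from = el[, 1], to = el[, 2],
                    weight = igraph::E(g)$weight, sign = igraph::E(g)$sign)
  out <- out[order(out$from, out$to), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
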