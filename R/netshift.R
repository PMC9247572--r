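neighbor_sets <- function(g) {
  ids <- igraph::V(g)$name
  stats::setNames(lapply(ids, function(v)
    igraph::V(g)$name[igraph::neighbors(g, v)]), ids)
}

#' NESH scores from neighbor-set summaries
#'
#' Neighbor-shift score of a node between a control (BT) and case (AT)
#' network, from its case-exclusive neighbor count: the sum of the
#' case-exclusive neighbor fraction `excl/nAT`, the union-normalized
#' exclusivity `excl/(nBT + excl)`, and a network-level term `excl/K` with K
#' the maximum case-exclusive count over all compared nodes.  Terms with a
#' zero denominator contribute 0.
#'
#' @param n_bt,n_at Neighbor counts in the control and case network.
#' @param exclusive Case-exclusive neighbor counts.
#' @param K Network-level normalizer; default `max(exclusive)`.
#' @return Numeric vector of NESH scores (>= 0).
#' @export
nesh_score <- function(n_bt, n_at, exclusive, K = max(exclusive)) {
  union_size <- n_bt + exclusive
  term <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, num / den, 0)
  }
  term(exclusive, n_at) + term(exclusive, union_size) + term(exclusive, K)
}

#' Driver calls from NESH and delta-betweenness
#'
#' A node is a driver when its NESH score reaches the `nesh_quantile`
#' quantile of all NESH scores, or its delta betweenness is positive.
#'
#' @param nesh Numeric NESH scores.
#' @param delbet Delta-betweenness values.
#' @param nesh_quantile Quantile defining "high NESH" (default 0.9).
#' @return Logical driver flags.
#' @export
call_drivers <- function(nesh, delbet, nesh_quantile = 0.9) {
  thr <- stats::quantile(nesh, nesh_quantile, names = FALSE)
  nesh >= thr | delbet > 0
}

#' NetShift-style comparison of a control and a case network
#'
#' For every node present in either network, compares its neighbor set A in
#' the control (BT) network with B in the case (AT) network: neighbor counts,
#' shared and case-exclusive neighbors, neighborhood Jaccard (intersection
#' over union), the NESH score ([nesh_score()]), and DelBet, the
#' difference in normalized betweenness (case minus control, each computed
#' within its own network; absent nodes contribute 0).  Positive DelBet
#' values are rescaled so their maximum is 1 when `rescale_delbet` is TRUE.
#' Drivers are called with [call_drivers()].  When the case network carries
#' modules, `core_at` counts a node's case neighbors in its own module.
#'
#' @param net_bt,net_at `co_network` objects (control and case).
#' @param nesh_quantile Quantile for the high-NESH driver rule.
#' @param rescale_delbet Rescale positive DelBet to max 1 (default TRUE).
#' @return Data frame of class `netshift_report`, one row per node:
#'   `asv_id`, `n_bt`, `n_at`, `core_at`, `shared`, `exclusive_at`,
#'   `jaccard`, `nesh`, `delbet`, `is_driver`.
#' @export
netshift_compare <- function(net_bt, net_at, nesh_quantile = 0.9,
                             rescale_delbet = TRUE) {
  g_bt <- if (inherits(net_bt, "co_network")) net_bt$graph else net_bt
  g_at <- if (inherits(net_at, "co_network")) net_at$graph else net_at
  nodes <- union(igraph::V(g_bt)$name, igraph::V(g_at)$name)
  if (length(nodes) == 0) stop("both networks are empty")
  nb_bt <- neighbor_sets(g_bt)
  nb_at <- neighbor_sets(g_at)
  get <- function(l, v) if (v %in% names(l)) l[[v]] else character(0)

  A <- lapply(nodes, function(v) get(nb_bt, v))
  B <- lapply(nodes, function(v) get(nb_at, v))
  n_bt <- lengths(A)
  n_at <- lengths(B)
  shared <- mapply(function(a, b) length(intersect(a, b)), A, B)
  excl <- n_at - shared
  union_size <- n_bt + excl
  jaccard <- ifelse(union_size > 0, shared / union_size, 0)
  nesh <- nesh_score(n_bt, n_at, excl)

  bet <- function(g, v) {
    b <- stats::setNames(rep(0, length(nodes)), nodes)
    if (igraph::gorder(g) > 2) {
      bb <- igraph::betweenness(g, normalized = TRUE, weights = NA)
      b[names(bb)] <- bb
    }
    b
  }
  delbet <- unname(bet(g_at)[nodes] - bet(g_bt)[nodes])
  if (rescale_delbet && any(delbet > 0))
    delbet[delbet > 0] <- delbet[delbet > 0] / max(delbet[delbet > 0])

  core_at <- rep(NA_integer_, length(nodes))
  modules_at <- if (inherits(net_at, "co_network")) net_at$modules else NULL
  if (!is.null(modules_at)) {
    mod_of <- stats::setNames(modules_at$module, modules_at$asv_id)
    core_at <- mapply(function(v, b) {
      if (!v %in% names(mod_of)) return(NA_integer_)
      sum(mod_of[b] == mod_of[[v]], na.rm = TRUE)
    }, nodes, B)
  }

  out <- data.frame(asv_id = nodes, n_bt = n_bt, n_at = n_at,
                    core_at = core_at, shared = shared, exclusive_at = excl,
                    jaccard = jaccard, nesh = nesh, delbet = delbet,
                    row.names = NULL)
  out$is_driver <- call_drivers(out$nesh, out$delbet, nesh_quantile)
  out <- out[order(-out$delbet, -out$nesh), ]
  rownames(out) <- NULL
  class(out) <- c("netshift_report", "data.frame")
  out
}
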