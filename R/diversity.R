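#' Per-sample alpha diversity
#'
#' Richness is the number of ASVs with count > 0; Shannon H uses natural
#' logarithms (H = -sum p log p over nonzero proportions).
#'
#' @param table A [count_table].
#' @return Data frame: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (any(colSums(x) == 0))
    warning("all-zero sample(s): richness 0, Shannon 0")
  data.frame(sample_id = colnames(x),
             richness = colSums(x > 0),
             shannon = vegan::diversity(t(x), index = "shannon"),
             row.names = NULL)
}

#' Analytic rarefaction curves
#'
#' Expected richness at each depth from the hypergeometric form
#' E[S_d] = sum_i (1 - choose(N - n_i, d)/choose(N, d)), via `vegan::rarefy`.
#' Depths exceeding a sample's total are clipped to the total with a warning.
#'
#' @param table A [count_table].
#' @param depths Increasing integer sequencing depths.
#' @return Long data frame: `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(table, depths) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  stopifnot(all(depths >= 1), !is.unsorted(depths))
  totals <- colSums(x)
  out <- lapply(colnames(x), function(s) {
    d <- depths
    if (any(d > totals[s])) {
      warning("depths beyond total reads clipped for sample ", s)
      d <- pmin(d, totals[s])
    }
    er <- vapply(d, function(dep)
      as.numeric(suppressWarnings(
        vegan::rarefy(t(x[, s, drop = FALSE]), sample = dep))),
      numeric(1))
    data.frame(sample_id = s, depth = d, expected_richness = er)
  })
  do.call(rbind, out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a,b) = 1 - 2 sum min(x_ia, x_ib) / (sum x_ia + sum x_ib), computed with
#' `vegan::vegdist`.  Pairs of all-zero samples get distance 0 with a
#' warning (Bray-Curtis is undefined there).
#'
#' @param table A [count_table], `rel_abundance`, or ASV-by-sample matrix.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts
       else if (inherits(table, "rel_abundance")) table$proportions
       else as.matrix(table)
  if (ncol(x) < 2) stop("need at least 2 samples")
  d <- vegan::vegdist(t(x), method = "bray")
  if (any(is.nan(d))) {
    warning("all-zero sample pair(s): distance set to 0")
    d[is.nan(d)] <- 0
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix: double-centered matrix
#' eigendecomposition, axes built from positive eigenvalues only; negative
#' eigenvalues are reported unchanged (no Cailliez correction).
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param k Maximum number of axes (default: all positive-eigenvalue axes).
#' @return List of class `ordination`: `coordinates` (samples x axes, ordered
#'   by descending eigenvalue), `eigenvalues` (all, including negatives),
#'   `method = "PCoA"`.
#' @export
pcoa <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-12)) stop("distance matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > max(eig) * 1e-9)
  if (is.null(k)) k <- pos else k <- min(k, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eig, method = "PCoA"),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via `vegan::metaMDS` (iterative majorization with
#' monotone regression, best of `restarts` random starts).  When the
#' originating abundance table is supplied, ASV scores are added as
#' weighted-average projections onto the sample configuration.
#'
#' @param d A `dist` over samples.
#' @param k Number of dimensions.
#' @param restarts Number of random starts.
#' @param table Optional [count_table] / `rel_abundance` for species scores.
#' @param seed Integer seed.
#' @return List of class `ordination`: `coordinates`, `stress`,
#'   `species_scores` (or `NULL`), `converged`, `method = "NMDS"`.
#' @export
nmds <- function(d, k = 2, restarts = 20, table = NULL, seed = 1) {
  stopifnot(k >= 1)
  set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(d, k = k, trymax = restarts,
                                         trace = 0, autotransform = FALSE,
                                         wascores = FALSE))
  coords <- fit$points
  colnames(coords) <- paste0("NMDS", seq_len(k))
  species <- NULL
  if (!is.null(table)) {
    x <- if (inherits(table, "count_table")) table$counts
         else if (inherits(table, "rel_abundance")) table$proportions
         else as.matrix(table)
    species <- vegan::wascores(coords, t(x))
  }
  structure(list(coordinates = coords, stress = fit$stress,
                 species_scores = species, converged = fit$converged > 0,
                 method = "NMDS"),
            class = "ordination")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from within/between sums of squared distances with an empirical
#' permutation p-value, p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations),
#' via `vegan::adonis2`.  Labels are permuted freely by default; pass
#' `strata` (e.g. subject ids) for a restricted, within-subject permutation
#' scheme matching a paired design.
#'
#' @param d A `dist` over samples.
#' @param groups Per-sample group labels (>= 2 groups, each >= 2 samples).
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @param strata Optional blocking factor restricting permutations.
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1, strata = NULL) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("each group needs at least 2 samples")
  set.seed(seed)
  dat <- data.frame(groups = groups)
  perm <- if (is.null(strata)) n_permutations else
    permute::how(blocks = strata, nperm = n_permutations)
  fit <- vegan::adonis2(d ~ groups, data = dat, permutations = perm)
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
                 n_permutations = n_permutations),
            class = "permanova_result")
}

#' Per-ASV rank-sum differential abundance
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per ASV between two
#' groups, with tie correction, plus Benjamini-Hochberg adjusted p-values.
#' Constant ASVs get p = 1.
#'
#' @param table A `rel_abundance`, [count_table], or matrix (features x
#'   samples).
#' @param groups Two-level per-sample labels.
#' @return Data frame: `asv_id`, `statistic` (U for the first level), `p`,
#'   `p_adj`.
#' @export
rank_sum_differential <- function(table, groups) {
  x <- if (inherits(table, "rel_abundance")) table$proportions
       else if (inherits(table, "count_table")) table$counts
       else as.matrix(table)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- groups == levels(groups)[1]
  res <- t(apply(x, 1, function(v) {
    if (stats::sd(v) == 0) return(c(sum(g1) * sum(!g1) / 2, 1))
    w <- suppressWarnings(stats::wilcox.test(v[g1], v[!g1]))
    c(unname(w$statistic), w$p.value)
  }))
  data.frame(asv_id = rownames(x), statistic = res[, 1], p = res[, 2],
             p_adj = stats::p.adjust(res[, 2], method = "BH"),
             row.names = NULL)
}
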