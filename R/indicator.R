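indval_matrix <- function(props, states) {
  # A (specificity): mean abundance in state / sum of state means
  # B (fidelity): occurrence fraction within state; IndVal = A * B
  lev <- levels(states)
  means <- vapply(lev, function(s) rowMeans(props[, states == s, drop = FALSE]),
                  numeric(nrow(props)))
  occ <- vapply(lev, function(s) rowMeans(props[, states == s, drop = FALSE] > 0),
                numeric(nrow(props)))
  tot <- rowSums(means)
  A <- means / ifelse(tot > 0, tot, 1)
  A * occ
}

#' Indicator species analysis (IndVal)
#'
#' IndVal_ik = A_ik * B_ik where A is the specificity (the ASV's mean
#' abundance in state k over the sum of its state means) and B the fidelity
#' (fraction of state-k samples where it occurs).  Significance per ASV and
#' state comes from permuting state labels:
#' p = (1 + #{IndVal_null >= IndVal_obs}) / (1 + n_permutations).
#'
#' @param table A `rel_abundance`, [count_table], or matrix.
#' @param states Two-level per-sample state labels.
#' @param n_permutations Label permutations.
#' @param seed Integer seed.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data frame of class `indicator_result`: `asv_id`, `state`,
#'   `indval`, `p`, `significant`; ASVs absent everywhere are skipped.
#' @export
indicator_species <- function(table, states, n_permutations = 10000, seed = 1,
                              alpha = 0.05) {
  props <- if (inherits(table, "rel_abundance")) table$proportions
           else if (inherits(table, "count_table")) to_relative(table)$proportions
           else as.matrix(table)
  states <- droplevels(as.factor(states))
  if (nlevels(states) != 2) stop("exactly two states required")
  present <- rowSums(props) > 0
  props <- props[present, , drop = FALSE]
  obs <- indval_matrix(props, states)
  set.seed(seed)
  exceed <- matrix(0, nrow(obs), ncol(obs))
  for (b in seq_len(n_permutations)) {
    null <- indval_matrix(props, sample(states))
    exceed <- exceed + (null >= obs)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  out <- data.frame(asv_id = rep(rownames(props), ncol(obs)),
                    state = rep(levels(states), each = nrow(obs)),
                    indval = as.vector(obs), p = as.vector(p),
                    row.names = NULL)
  out$significant <- out$p < alpha
  class(out) <- c("indicator_result", "data.frame")
  out
}
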