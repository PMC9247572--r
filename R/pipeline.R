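#' Pipeline configuration
#'
#' One declarative object for [run_pipeline()]: either a
#' [simulation_config()] or paths to count/metadata TSVs, plus every stage
#' threshold and permutation count.  A single `seed` is fanned out to the
#' stages by fixed offsets (seed + 1, + 2, ...), so one number reproduces the
#' whole run.
#'
#' @param sim_config A [simulation_config()] (used when paths are NULL).
#' @param counts_path,metadata_path Input TSVs (alternative to simulation).
#' @param out_dir Output directory for per-stage artifacts; `NULL` disables
#'   writing.
#' @param min_prevalence,min_total_relabund,filter_rule ASV filter settings
#'   (see [filter_asvs()]).
#' @param rho_min,alpha Network edge inclusion rule.
#' @param network_top_n Networks are built on at most this many ASVs (the
#'   most abundant by mean relative abundance within each state), keeping
#'   the co-occurrence stage at the scale of a dominant-community subnetwork.
#' @param nesh_quantile High-NESH driver quantile.
#' @param n_permutations PERMANOVA / indicator permutations.
#' @param sparcc_iterations,sparcc_bootstraps SparCC settings.
#' @param cscore_nulls,niche_nulls Assembly null-model sizes.
#' @param run_niche Run the (relatively slow) niche classification stage.
#' @param rf_trees Random-forest size.
#' @param glm_bootstraps Bootstrap resamples for the covariate regression.
#' @param glm_max_size Largest covariate subset scored by [all_subsets()].
#' @param focal_asv ASV id for the covariate regression; `NULL` uses the
#'   simulation's focal ASV (synthetic input) or the top driver.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim_config = NULL, counts_path = NULL,
                            metadata_path = NULL, out_dir = NULL,
                            min_prevalence = 0.20, min_total_relabund = 0.025,
                            filter_rule = "or",
                            rho_min = 0.3, alpha = 0.05, network_top_n = 150,
                            nesh_quantile = 0.9,
                            n_permutations = 999,
                            sparcc_iterations = 10, sparcc_bootstraps = 50,
                            cscore_nulls = 1000, niche_nulls = 200,
                            run_niche = TRUE, rf_trees = 500,
                            glm_bootstraps = 999, glm_max_size = 4,
                            focal_asv = NULL, seed = 1) {
  if (is.null(sim_config) && (is.null(counts_path) || is.null(metadata_path)))
    stop("either sim_config or counts_path + metadata_path is required")
  structure(as.list(environment()), class = "pipeline_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_artifact <- function(obj, out_dir, file) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full driver-taxon pipeline
#'
#' Simulate or ingest a paired BT/AT cohort, then: filter and TMM-normalize;
#' alpha/beta diversity, PCoA, PERMANOVA, NMDS, rank-sum differential
#' abundance; per-state Sloan NCM fits, C-score SES, and (optionally) niche
#' classification; per-state SparCC networks with modules and metrics;
#' indicator species; NetShift comparison with driver calls and the common
#' subnetwork; random-forest state classification; and the all-subsets +
#' negative-binomial covariate regression on the focal ASV.  Per-stage TSVs
#' and a `summary.json` are written under `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results plus `summary` (the machine-readable
#'   digest) and `resolved_config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  s <- config$seed
  res <- list(resolved_config = config)

  dataset <- NULL
  tab <- with_stage("input", {
    if (!is.null(config$counts_path)) {
      if (!file.exists(config$counts_path))
        stop("missing input path: ", config$counts_path)
      read_count_table(config$counts_path, config$metadata_path)
    } else {
      dataset <- simulate_paired_cohort(config$sim_config)
      dataset$table
    }
  })
  res$dataset <- dataset
  states <- tab$metadata$state

  filtered <- with_stage("filter", suppressMessages(
    filter_asvs(tab, config$min_prevalence, config$min_total_relabund,
                rule = config$filter_rule)))
  normalized <- with_stage("normalize", tmm_normalize(filtered))
  rel <- to_relative(filtered)
  res$filtered <- filtered

  res$alpha <- with_stage("diversity", alpha_diversity(filtered))
  d_bray <- with_stage("diversity", bray_curtis(rel))
  res$pcoa <- with_stage("diversity", pcoa(d_bray))
  res$permanova <- with_stage("diversity",
    permanova(d_bray, states, config$n_permutations, seed = s + 1))
  res$nmds <- with_stage("diversity",
    nmds(d_bray, table = rel, seed = s + 2))
  res$differential <- with_stage("diversity", rank_sum_differential(rel, states))

  group_tables <- lapply(c(BT = "BT", AT = "AT"), function(st)
    filtered$counts[, states == st, drop = FALSE])

  res$ncm <- with_stage("assembly",
    lapply(group_tables, function(x) fit_ncm(x[rowSums(x) > 0, , drop = FALSE])))
  res$cscore <- with_stage("assembly", lapply(group_tables, function(x) {
    pres <- (x > 0)[rowSums(x > 0) > 0, , drop = FALSE]
    c_score_ses(pres, n_null = config$cscore_nulls, seed = s + 3)
  }))
  if (config$run_niche)
    res$niche <- with_stage("assembly", lapply(group_tables, function(x)
      classify_niche(x[rowSums(x) > 0, , drop = FALSE],
                     n_null = max(100, config$niche_nulls), seed = s + 4)))

  nets <- with_stage("networks", {
    lapply(stats::setNames(names(group_tables), names(group_tables)), function(st) {
      x <- group_tables[[st]]
      x <- x[rowSums(x) > 0, , drop = FALSE]
      if (nrow(x) > config$network_top_n) {
        rel_mean <- rowMeans(sweep(x, 2, pmax(colSums(x), 1), "/"))
        x <- x[order(-rel_mean)[seq_len(config$network_top_n)], , drop = FALSE]
      }
      offset <- if (st == "BT") 5 else 6
      rho <- sparcc(x, n_iterations = config$sparcc_iterations, seed = s + offset)
      pmat <- edge_significance(x, rho, n_bootstraps = config$sparcc_bootstraps,
                                seed = s + offset + 2,
                                n_iterations = config$sparcc_iterations)
      net <- build_network(rho, pmat, rho_min = config$rho_min,
                           alpha = config$alpha)
      if (igraph::gsize(net$graph) > 0) net <- detect_modules(net, seed = s + 9)
      net
    })
  })
  res$networks <- nets
  res$network_metrics <- lapply(nets, function(n)
    if (igraph::gorder(n$graph) >= 2) network_metrics(n) else NULL)

  res$indicators <- with_stage("indicator",
    indicator_species(rel, states, n_permutations = config$n_permutations,
                      seed = s + 10))

  res$netshift <- with_stage("netshift",
    netshift_compare(nets$BT, nets$AT, nesh_quantile = config$nesh_quantile))
  res$common <- with_stage("netshift", common_subnetwork(nets$BT, nets$AT))

  res$classifier <- with_stage("models",
    rf_classify(normalized, states, n_trees = config$rf_trees, seed = s + 11))

  covariate_names <- c("age", "height", "weight", "education", "flavor",
                       "fruit_veg", "smoking", "drinking", "exercise", "sleep")
  covariate_names <- intersect(covariate_names, names(tab$metadata))
  res$glm <- NULL
  if (length(covariate_names) >= 2) {
    focal <- config$focal_asv
    if (is.null(focal) && !is.null(dataset))
      focal <- asv_names(dataset$truth$config$n_asvs)[dataset$truth$focal_asv]
    if (is.null(focal)) focal <- res$netshift$asv_id[1]
    if (focal %in% rownames(tab$counts)) {
      bt <- tab$metadata$state == "BT"
      y <- tab$counts[focal, bt]
      X <- tab$metadata[bt, covariate_names, drop = FALSE]
      X <- X[, vapply(X, function(v) stats::sd(as.numeric(v)) > 0, logical(1)),
             drop = FALSE]
      res$glm <- with_stage("models", {
        subsets <- all_subsets(y, X, max_size = config$glm_max_size)
        best <- subsets$subset[which.max(subsets$adj_r2)]
        vars <- if (best == "(none)") character(0) else
          strsplit(best, ",", fixed = TRUE)[[1]]
        fit <- if (length(vars) > 0)
          negbin_glm(y, X[, vars, drop = FALSE],
                     n_bootstrap = config$glm_bootstraps, seed = s + 12)
        list(focal_asv = focal, subsets = subsets, selected = vars, fit = fit)
      })
    }
  }

  res$summary <- list(
    n_asvs_input = nrow(tab$counts),
    n_asvs_filtered = nrow(filtered$counts),
    permanova = list(F = res$permanova$pseudo_F, R2 = res$permanova$R2,
                     p = res$permanova$p),
    ncm = lapply(res$ncm, function(f) list(Nm = f$Nm, R2 = f$R2)),
    cscore_ses = lapply(res$cscore, function(cs) cs$SES),
    network = lapply(res$network_metrics, function(m)
      if (is.null(m)) NULL else as.list(m)),
    drivers = res$netshift$asv_id[res$netshift$is_driver],
    auc = res$classifier$auc,
    glm_terms = if (!is.null(res$glm) && !is.null(res$glm$fit))
      res$glm$fit$coefficients$term[-1] else character(0))

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    write_artifact(res$alpha, out, "alpha_diversity.tsv")
    write_artifact(res$differential, out, "differential_abundance.tsv")
    write_artifact(as.data.frame(res$netshift), out, "netshift_report.tsv")
    write_artifact(res$common$edges, out, "common_subnetwork.tsv")
    write_artifact(res$classifier$importance, out, "rf_importance.tsv")
    for (st in names(nets))
      if (igraph::gsize(nets[[st]]$graph) > 0)
        write_network(nets[[st]], file.path(out, paste0("network_", st, ".tsv")))
    jsonlite::write_json(res$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(config[!vapply(config, is.null, logical(1)) &
                                  names(config) != "sim_config"],
                         file.path(out, "resolved_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res
}
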