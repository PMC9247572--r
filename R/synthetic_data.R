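#' Configuration for the paired-cohort simulator
#'
#' Defaults emulate a paired gut-microbiome study design: 25 subjects sampled
#' once before (BT) and once after (AT) treatment, sequencing depth around
#' 29,319 reads per sample with negative-binomial overdispersion, and a
#' log-normal source community over a few thousand ASVs.
#'
#' @param n_subjects Number of paired subjects (each contributes one BT and
#'   one AT sample).
#' @param n_asvs Number of ASVs in the community.
#' @param library_size_mean Mean reads per sample.
#' @param library_size_dispersion Negative-binomial size parameter for the
#'   per-sample depth draw (smaller = more overdispersed).
#' @param source_community Optional probability vector over ASVs (sums to 1).
#'   When `NULL`, a log-normal (sdlog = 2) profile is drawn from the seed.
#' @param migration_Nm Sloan N*m used by [simulate_neutral_community()].
#' @param planted_modules List of `list(asvs =, r =, state =)` correlation
#'   plants: latent (Gaussian-copula) pairwise correlation `r` among the
#'   given ASVs, induced only in `state` (`"BT"`, `"AT"`, or `"both"`).
#' @param planted_differential List of `list(asv =, lfc =)`: log2 fold change
#'   applied multiplicatively in AT.
#' @param planted_indicators List of `list(asv =, state =)`: ASV present only
#'   in the given state.
#' @param covariate_effects Named numeric vector of coefficients on the focal
#'   ASV's log-mean, per standardized covariate (names must match metadata
#'   covariate columns, e.g. `fruit_veg`, `flavor`, `age`).
#' @param focal_asv Index of the ASV receiving covariate effects.
#' @param baseline_sdlog,subject_sdlog,noise_sdlog Log-scale spread of the
#'   community profile, of between-subject effects, and of per-sample noise.
#' @param seed Integer seed; fully determines the draw.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 25,
                              n_asvs = 2000,
                              library_size_mean = 29319,
                              library_size_dispersion = 5,
                              source_community = NULL,
                              migration_Nm = 1000,
                              planted_modules = list(),
                              planted_differential = list(),
                              planted_indicators = list(),
                              covariate_effects = numeric(0),
                              focal_asv = 1,
                              baseline_sdlog = 2,
                              subject_sdlog = 0.4,
                              noise_sdlog = 0.3,
                              seed = 1) {
  stopifnot(n_subjects >= 1, n_asvs >= 2,
            library_size_mean > 0, library_size_dispersion > 0)
  if (!is.finite(migration_Nm) || migration_Nm <= 0)
    stop("migration_Nm must be a positive finite number")
  if (!is.null(source_community)) {
    stopifnot(length(source_community) == n_asvs, all(source_community >= 0))
    if (abs(sum(source_community) - 1) > 1e-9)
      stop("source_community must sum to 1")
  }
  check_idx <- function(i) {
    if (any(i < 1 | i > n_asvs)) stop("planted ASV index out of range")
  }
  for (m in planted_modules) {
    check_idx(m$asvs)
    stopifnot(abs(m$r) <= 1, m$state %in% c("BT", "AT", "both"))
  }
  for (d in planted_differential) check_idx(d$asv)
  for (p in planted_indicators) {
    check_idx(p$asv)
    stopifnot(p$state %in% c("BT", "AT"))
  }
  diff_asvs <- vapply(planted_differential, `[[`, numeric(1), "asv")
  ind_asvs <- vapply(planted_indicators, `[[`, numeric(1), "asv")
  if (length(intersect(diff_asvs, ind_asvs)) > 0)
    stop("conflicting plants: ASV(s) ",
         paste(intersect(diff_asvs, ind_asvs), collapse = ", "),
         " are both differential and indicator")
  for (st in c("BT", "AT")) {
    in_state <- unlist(lapply(planted_modules, function(m)
      if (m$state %in% c(st, "both")) m$asvs else integer(0)))
    if (anyDuplicated(in_state))
      stop("conflicting plants: ASV in two correlation modules active in ", st)
  }
  structure(list(n_subjects = n_subjects, n_asvs = n_asvs,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 source_community = source_community,
                 migration_Nm = migration_Nm,
                 planted_modules = planted_modules,
                 planted_differential = planted_differential,
                 planted_indicators = planted_indicators,
                 covariate_effects = covariate_effects,
                 focal_asv = focal_asv,
                 baseline_sdlog = baseline_sdlog,
                 subject_sdlog = subject_sdlog,
                 noise_sdlog = noise_sdlog,
                 seed = seed),
            class = "simulation_config")
}

asv_names <- function(n) sprintf("ASV%d", seq_len(n))

draw_library_sizes <- function(n, mean, size) {
  pmax(stats::rnbinom(n, mu = mean, size = size), 100L)
}

draw_source <- function(config) {
  if (!is.null(config$source_community)) return(config$source_community)
  w <- stats::rlnorm(config$n_asvs, meanlog = 0, sdlog = 2)
  w / sum(w)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

cohort_metadata <- function(n_subjects) {
  subj <- sprintf("S%02d", seq_len(n_subjects))
  covs <- data.frame(
    subject = subj,
    age = round(stats::runif(n_subjects, 18, 70)),
    height = round(stats::rnorm(n_subjects, 170, 8), 1),
    weight = round(stats::rnorm(n_subjects, 65, 12), 1),
    education = sample(1:4, n_subjects, replace = TRUE),
    flavor = sample(1:3, n_subjects, replace = TRUE),      # dietary flavor strength
    fruit_veg = sample(1:3, n_subjects, replace = TRUE),   # fruit/vegetable intake
    smoking = stats::rbinom(n_subjects, 1, 0.4),
    drinking = stats::rbinom(n_subjects, 1, 0.3),
    exercise = sample(1:3, n_subjects, replace = TRUE),
    sleep = sample(1:3, n_subjects, replace = TRUE),
    stringsAsFactors = FALSE)
  meta <- rbind(
    data.frame(sample_id = paste0(subj, "_BT"), state = "BT", covs),
    data.frame(sample_id = paste0(subj, "_AT"), state = "AT", covs))
  rownames(meta) <- meta$sample_id
  meta
}

finish_dataset <- function(counts, meta, truth) {
  tab <- count_table(counts, meta)
  structure(list(table = tab,
                 counts_bt = counts[, meta$state == "BT", drop = FALSE],
                 counts_at = counts[, meta$state == "AT", drop = FALSE],
                 metadata = tab$metadata,
                 truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d ASVs x %d samples (%d BT / %d AT)\n",
              nrow(x$table$counts), ncol(x$table$counts),
              ncol(x$counts_bt), ncol(x$counts_at)))
  invisible(x)
}

#' Simulate a neutrally assembled community
#'
#' Every sample's relative abundances are drawn from a Dirichlet with
#' concentration `Nm * source_community` (Sloan neutral model at migration
#' parameter N*m), then reads are drawn multinomially at a negative-binomial
#' library size.  Column sums equal the drawn library sizes exactly.
#'
#' @param config A [simulation_config()]; `migration_Nm` and
#'   `source_community` govern the draw.
#' @return A `synthetic_dataset`; `truth$Nm` records the generating N*m.
#' @export
simulate_neutral_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  meta <- cohort_metadata(config$n_subjects)
  n_samples <- nrow(meta)
  source <- draw_source(config)
  lib <- draw_library_sizes(n_samples, config$library_size_mean,
                            config$library_size_dispersion)
  counts <- matrix(0, config$n_asvs, n_samples,
                   dimnames = list(asv_names(config$n_asvs), meta$sample_id))
  for (j in seq_len(n_samples)) {
    rel <- rdirichlet1(config$migration_Nm * source)
    counts[, j] <- stats::rmultinom(1, lib[j], rel)
  }
  finish_dataset(counts, meta,
                 list(Nm = config$migration_Nm, source_community = source,
                      library_sizes = stats::setNames(lib, meta$sample_id),
                      config = config))
}

#' Simulate a paired BT/AT cohort with planted structure
#'
#' Each subject gets a log-normal baseline abundance profile; planted log2
#' fold changes act multiplicatively in AT, planted correlation modules
#' induce pairwise latent (Gaussian-copula) correlation only in their state,
#' planted indicator ASVs are present only in their state, and covariate
#' effects enter the focal ASV's log-mean linearly (on standardized
#' covariates).  Counts are multinomial draws at negative-binomial depths, so
#' marginal count distributions are preserved under the copula plants.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset` whose `truth` element records every plant.
#' @export
simulate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  meta <- cohort_metadata(config$n_subjects)
  n_samples <- nrow(meta)
  p <- config$n_asvs

  base <- if (!is.null(config$source_community)) {
    log(pmax(config$source_community, 1e-12))
  } else {
    stats::rnorm(p, 0, config$baseline_sdlog)
  }
  subj_eff <- matrix(stats::rnorm(p * config$n_subjects, 0, config$subject_sdlog),
                     p, config$n_subjects)
  subj_idx <- match(meta$subject, unique(meta$subject))

  logmean <- base + subj_eff[, subj_idx] +
    config$noise_sdlog * matrix(stats::rnorm(p * n_samples), p, n_samples)

  # copula-correlated blocks: inside a planted module (in its state) the whole
  # per-sample log deviation is rebuilt from a shared latent factor so that
  # the pairwise correlation of member log-abundances across samples is ~ r
  sd_tot <- sqrt(config$subject_sdlog^2 + config$noise_sdlog^2)
  for (m in config$planted_modules) {
    in_state <- if (m$state == "both") rep(TRUE, n_samples) else meta$state == m$state
    z <- stats::rnorm(sum(in_state))
    r <- abs(m$r)
    # member k loads on the shared factor; alternating signs when r < 0
    sgn <- if (m$r < 0) rep_len(c(1, -1), length(m$asvs)) else rep(1, length(m$asvs))
    eps <- matrix(stats::rnorm(length(m$asvs) * sum(in_state)),
                  length(m$asvs), sum(in_state))
    dev <- sd_tot * (outer(sgn * sqrt(r), z) + sqrt(1 - r) * eps)
    logmean[m$asvs, in_state] <- base[m$asvs] + dev
  }

  for (d in config$planted_differential)
    logmean[d$asv, meta$state == "AT"] <-
      logmean[d$asv, meta$state == "AT"] + d$lfc * log(2)

  if (length(config$covariate_effects) > 0) {
    for (cv in names(config$covariate_effects)) {
      if (!cv %in% names(meta)) stop("unknown covariate in effects: ", cv)
      x <- as.numeric(meta[[cv]])
      xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
      logmean[config$focal_asv, ] <- logmean[config$focal_asv, ] +
        config$covariate_effects[[cv]] * xs
    }
  }

  abun <- exp(logmean)
  for (ind in config$planted_indicators) {
    abun[ind$asv, meta$state != ind$state] <- 0
    # detectable in its own state: lift to the community's upper quartile
    lift <- stats::quantile(exp(base), 0.75)
    abun[ind$asv, meta$state == ind$state] <-
      pmax(abun[ind$asv, meta$state == ind$state], lift)
  }

  lib <- draw_library_sizes(n_samples, config$library_size_mean,
                            config$library_size_dispersion)
  counts <- matrix(0, p, n_samples,
                   dimnames = list(asv_names(p), meta$sample_id))
  for (j in seq_len(n_samples))
    counts[, j] <- stats::rmultinom(1, lib[j], abun[, j] / sum(abun[, j]))

  finish_dataset(counts, meta,
                 list(modules = config$planted_modules,
                      differential = config$planted_differential,
                      indicators = config$planted_indicators,
                      covariate_effects = config$covariate_effects,
                      focal_asv = config$focal_asv,
                      library_sizes = stats::setNames(lib, meta$sample_id),
                      config = config))
}
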