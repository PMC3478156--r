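#' Expression archetypes of the silicon response
#'
#' Per-timepoint log2 levels (relative to a gene's own baseline) over the
#' hours {0, 2, 4, 7, 8, 9}. The `silaffin` shape follows the Tpsil3 marker:
#' transient up-regulation while girdle bands are made (2 h), a dip during
#' S phase (4 h), strong up-regulation during valve formation (7-8 h) and
#' decline after cell separation. `starvation` genes are high only in the
#' arrested 0 h culture. `sit1`/`sit2` are distinct non-flat transporter-like
#' shapes (profile correlation ~0.77, below the default cluster threshold),
#' `flat` is all-zero, and `random` draws an independent shape per gene.
#' Magnitudes are free parameters of the generator, not measured values.
#'
#' @return Named list of numeric length-6 vectors (plus the `random` marker
#'   entry, which is resolved per gene at generation time).
#' @export
archetype_specs <- function() {
  hours <- as.character(design_hours())
  mk <- function(v) stats::setNames(v, hours)
  list(
    silaffin   = mk(c(0, 1, 0, 3, 3, 0.5)),
    starvation = mk(c(2, 0, 0, 0, 0, 0)),
    sit1       = mk(c(0.5, 2, 2.5, 1, 0.5, 0)),
    sit2       = mk(c(1, 1, 2.5, 2, 0.5, 0)),
    flat       = mk(rep(0, 6)),
    random     = NULL
  )
}

#' Configuration for the expression-matrix generator
#'
#' @param n_genes number of genes.
#' @param probes_per_gene probes per gene (default 16, the array's average).
#' @param archetype_mixture named fractions over [archetype_specs()] names;
#'   must sum to 1. The default emulates realistic proportions: a few
#'   percent of valve-formation and starvation responders, small
#'   transporter-like groups, a majority of unresponsive genes and a tail of
#'   miscellaneous regulation.
#' @param probe_affinity_sd SD (log2 units) of the per-probe affinity offset,
#'   constant across timepoints within a probe.
#' @param noise_sd SD (log2 units) of the measurement noise (additive on the
#'   log2 scale, i.e. log-normal intensities).
#' @param baseline_mean,baseline_sd per-gene baseline log2 level.
#' @param random_profile_sd SD of per-timepoint levels for `random` genes.
#' @param seed master seed; component substreams are derived from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_genes,
                             probes_per_gene = 16,
                             archetype_mixture = c(silaffin = 0.040,
                                                   starvation = 0.045,
                                                   sit1 = 0.010,
                                                   sit2 = 0.015,
                                                   flat = 0.640,
                                                   random = 0.250),
                             probe_affinity_sd = 0.25,
                             noise_sd = 0.25,
                             baseline_mean = 8,
                             baseline_sd = 1.5,
                             random_profile_sd = 1.5,
                             seed = 1L) {
  if (n_genes < 1 || probes_per_gene < 2) {
    stop("configuration error: n_genes >= 1 and probes_per_gene >= 2 required")
  }
  if (is.null(names(archetype_mixture)) ||
      !all(names(archetype_mixture) %in% names(archetype_specs()))) {
    stop("configuration error: unknown archetype in mixture")
  }
  if (abs(sum(archetype_mixture) - 1) > 1e-9) {
    stop("configuration error: archetype fractions must sum to 1")
  }
  if (any(archetype_mixture < 0)) {
    stop("configuration error: negative archetype fraction")
  }
  if (noise_sd < 0 || probe_affinity_sd < 0) {
    stop("configuration error: noise_sd and probe_affinity_sd must be >= 0")
  }
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 archetype_mixture = archetype_mixture,
                 probe_affinity_sd = probe_affinity_sd,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 random_profile_sd = random_profile_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic substream seed derivation from the master seed, keeping the
# components' draws independent of each other's draw counts.
substream_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 1000003) %% 2147483647)
}

# Largest-remainder apportionment of n genes to mixture fractions.
apportion <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic probe-level expression matrix with planted truth
#'
#' Intensities follow `2^(archetype level + gene baseline + probe affinity +
#' N(0, noise_sd))`: a multiplicative probe-affinity, log-normal-noise model
#' of a one-array-per-timepoint tiling design. The returned truth records
#' each gene's archetype, its true per-timepoint levels and true log2-ratio
#' profile, and whether it is truly flat, so every selection and clustering
#' stage can be scored against the planted labels.
#'
#' @param config a [generator_config()].
#' @return List with `matrix` (an `expr_matrix`) and `truth` (list with the
#'   per-gene `genes` data.frame, the `levels` matrix and the true
#'   `profiles` matrix of log2 ratios).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  hours <- design_hours()
  n <- config$n_genes
  np <- config$probes_per_gene
  nt <- length(hours)
  arch <- archetype_specs()
  mix <- config$archetype_mixture
  counts <- apportion(mix, n)
  labels <- rep(names(mix), counts)
  gene_ids <- sprintf("gene%05d", seq_len(n))

  # component substreams: archetype shapes, baselines, affinities, noise
  set.seed(substream_seed(config$seed, 1L))
  levels <- matrix(0, nrow = n, ncol = nt,
                   dimnames = list(gene_ids, as.character(hours)))
  for (a in names(mix)) {
    idx <- which(labels == a)
    if (length(idx) == 0) next
    if (a == "random") {
      levels[idx, ] <- matrix(stats::rnorm(length(idx) * nt, 0,
                                           config$random_profile_sd),
                              ncol = nt)
    } else {
      levels[idx, ] <- matrix(arch[[a]], nrow = length(idx), ncol = nt,
                              byrow = TRUE)
    }
  }
  set.seed(substream_seed(config$seed, 2L))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  set.seed(substream_seed(config$seed, 3L))
  affinity <- matrix(stats::rnorm(n * np, 0, config$probe_affinity_sd),
                     nrow = n, ncol = np)
  set.seed(substream_seed(config$seed, 4L))
  noise <- array(stats::rnorm(n * np * nt, 0, config$noise_sd),
                 dim = c(n, np, nt))

  # long table ordered gene x timepoint x probe
  gene_col <- rep(gene_ids, each = nt * np)
  hour_col <- rep(rep(hours, each = np), times = n)
  probe_col <- rep(sprintf("p%02d", seq_len(np)), times = n * nt)
  log2val <- rep(baseline, each = nt * np) +
    levels[cbind(rep(seq_len(n), each = nt * np),
                 rep(rep(seq_len(nt), each = np), times = n))] +
    affinity[cbind(rep(seq_len(n), each = nt * np),
                   rep(rep(seq_len(np), times = nt), times = n))] +
    noise[cbind(rep(seq_len(n), each = nt * np),
                rep(rep(seq_len(np), times = nt), times = n),
                rep(rep(seq_len(nt), each = np), times = n))]
  df <- data.frame(gene_id = gene_col,
                   probe_id = paste0(gene_col, "_", probe_col),
                   timepoint_h = hour_col,
                   intensity = 2^log2val,
                   stringsAsFactors = FALSE)

  profiles <- levels[, -1L, drop = FALSE] - levels[, 1L]
  truth <- list(
    genes = data.frame(gene_id = gene_ids,
                       archetype = labels,
                       flat = apply(abs(profiles), 1L, max) < 0.5,
                       stringsAsFactors = FALSE),
    levels = levels,
    profiles = profiles
  )
  list(matrix = expression_matrix(df, hours = hours), truth = truth)
}
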