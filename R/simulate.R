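#' Configuration for the synthetic RNA-seq count generator
#'
#' Collects and validates every parameter of the negative-binomial count
#' simulator. The defaults emulate the study design the analysis is built
#' for: two replicates per condition, a desk-scale transcriptome of
#' 10,000 genes, gene means drawn from a log-normal prior, and a planted
#' fraction of differentially expressed (DE) genes with a fixed absolute
#' log2 fold change of random sign.
#'
#' The negative-binomial noise uses the standard parameterization
#' `Var = mu + dispersion * mu^2`.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per condition (study design: 2).
#' @param baseline_mean_log_mu,baseline_mean_log_sigma meanlog and sdlog
#'   of the log-normal prior on gene mean expression (counts).
#' @param dispersion negative-binomial dispersion (must be > 0).
#' @param pi1 fraction of genes planted as DE, in `[0, 1]`.
#' @param effect_log2fc absolute log2 fold change of planted DE genes;
#'   the sign of each gene's effect is random.
#' @param library_size_cv coefficient of variation of the per-sample
#'   library size factors (0 = equal depth).
#' @param n_sets number of gene sets generated by
#'   [simulate_gene_sets()].
#' @param set_size genes per set; must not exceed `n_genes`.
#' @param enrichment_rho relative odds (>= 1) that a member of an
#'   enriched set is DE; 1 plants no enrichment.
#' @param n_enriched how many sets are planted as enriched; defaults to
#'   1 when `enrichment_rho > 1`, else 0.
#' @param rrna_fraction fraction of genes flagged as ribosomal RNA, in
#'   `[0, 1)`; the flag only marks genes for [filter_rrna()].
#' @param seed integer seed; the same config always yields the same data.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_counts()], [simulate_gene_sets()]
#' @export
sim_config <- function(n_genes = 10000L,
                       n_per_group = 2L,
                       baseline_mean_log_mu = log(100),
                       baseline_mean_log_sigma = 1.5,
                       dispersion = 0.1,
                       pi1 = 0.1,
                       effect_log2fc = 2.0,
                       library_size_cv = 0.1,
                       n_sets = 50L,
                       set_size = min(100L, n_genes),
                       enrichment_rho = 1,
                       n_enriched = if (enrichment_rho > 1) 1L else 0L,
                       rrna_fraction = 0.05,
                       seed = 1L) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", what)
  }
  chk(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1,
      "n_genes", "must be a positive integer")
  chk(is.numeric(n_per_group) && n_per_group >= 1,
      "n_per_group", "must be a positive integer")
  chk(is.numeric(baseline_mean_log_mu) && is.finite(baseline_mean_log_mu),
      "baseline_mean_log_mu", "must be finite")
  chk(is.numeric(baseline_mean_log_sigma) && baseline_mean_log_sigma >= 0,
      "baseline_mean_log_sigma", "must be nonnegative")
  chk(is.numeric(dispersion) && dispersion > 0,
      "dispersion", "must be strictly positive")
  chk(is.numeric(pi1) && pi1 >= 0 && pi1 <= 1, "pi1", "must be in [0, 1]")
  chk(pi1 == 0 || pi1 * n_genes >= 1,
      "pi1", "pi1 * n_genes must be >= 1 when pi1 > 0")
  chk(is.numeric(effect_log2fc) && effect_log2fc > 0,
      "effect_log2fc", "must be strictly positive")
  chk(is.numeric(library_size_cv) && library_size_cv >= 0,
      "library_size_cv", "must be nonnegative")
  chk(is.numeric(n_sets) && n_sets >= 0, "n_sets", "must be nonnegative")
  chk(is.numeric(set_size) && set_size >= 1, "set_size", "must be positive")
  chk(set_size <= n_genes, "set_size", "must not exceed n_genes")
  chk(is.numeric(enrichment_rho) && enrichment_rho >= 1,
      "enrichment_rho", "must be >= 1")
  chk(is.numeric(n_enriched) && n_enriched >= 0 && n_enriched <= n_sets,
      "n_enriched", "must be in [0, n_sets]")
  chk(is.numeric(rrna_fraction) && rrna_fraction >= 0 && rrna_fraction < 1,
      "rrna_fraction", "must be in [0, 1)")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be an integer")

  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    baseline_mean_log_mu = baseline_mean_log_mu,
    baseline_mean_log_sigma = baseline_mean_log_sigma,
    dispersion = dispersion, pi1 = pi1, effect_log2fc = effect_log2fc,
    library_size_cv = library_size_cv, n_sets = as.integer(n_sets),
    set_size = as.integer(set_size), enrichment_rho = enrichment_rho,
    n_enriched = as.integer(n_enriched), rrna_fraction = rrna_fraction,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a gene-by-sample count matrix with planted effects
#'
#' Draws a 2-group negative-binomial count matrix under the generative
#' model described in [sim_config()] and records the complete ground
#' truth. Gene means `mu_g` are log-normal; a Bernoulli(`pi1`) draw
#' selects DE genes, each given a log2 fold change of `+/- effect_log2fc`
#' (random sign) applied symmetrically around the baseline (treated mean
#' `mu_g * 2^(lfc/2)`, control mean `mu_g * 2^(-lfc/2)`); per-sample
#' library size factors are log-normal with the requested coefficient of
#' variation; counts are `NB(mean, dispersion)` with
#' `Var = mu + dispersion * mu^2`.
#'
#' @param config a [sim_config()].
#' @return A list of class `"sim_counts"` with elements
#'   \describe{
#'     \item{matrix}{a [count_matrix()] of `n_genes` x
#'       `2 * n_per_group` counts, samples labeled `treated`/`control`;}
#'     \item{truth}{a list of class `"sim_truth"`: `de_genes`
#'       (character), `signed_log2fc` (named numeric over all genes, 0
#'       for non-DE), `rrna_genes` (character), `size_factors`,
#'       `n_de` (realized planted count), and (after
#'       [simulate_gene_sets()]) `enriched_sets`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 7))
#' sim$matrix
#' length(sim$truth$de_genes)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  npg <- config$n_per_group
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  sample_ids <- c(sprintf("treated_%d", seq_len(npg)),
                  sprintf("control_%d", seq_len(npg)))
  groups <- stats::setNames(rep(c("treated", "control"), each = npg),
                            sample_ids)

  mu <- stats::rlnorm(n, config$baseline_mean_log_mu,
                      config$baseline_mean_log_sigma)
  de <- stats::rbinom(n, 1L, config$pi1) == 1L
  lfc <- numeric(n)
  lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) * config$effect_log2fc

  cv <- config$library_size_cv
  sf <- if (cv > 0) {
    sdl <- sqrt(log1p(cv^2))
    stats::rlnorm(2L * npg, -sdl^2 / 2, sdl)   # mean 1
  } else rep(1, 2L * npg)

  mean_treated <- mu * 2^(lfc / 2)
  mean_control <- mu * 2^(-lfc / 2)
  size <- 1 / config$dispersion
  counts <- matrix(0L, n, 2L * npg, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(2L * npg)) {
    m <- if (groups[j] == "treated") mean_treated else mean_control
    counts[, j] <- stats::rnbinom(n, mu = m * sf[j], size = size)
  }

  rrna <- stats::rbinom(n, 1L, config$rrna_fraction) == 1L
  names(rrna) <- gene_ids

  truth <- structure(list(
    de_genes = gene_ids[de],
    signed_log2fc = stats::setNames(lfc, gene_ids),
    rrna_genes = gene_ids[rrna],
    size_factors = stats::setNames(sf, sample_ids),
    n_de = sum(de),
    enriched_sets = character(0)), class = "sim_truth")

  structure(list(matrix = count_matrix(counts, groups, rrna = rrna),
                 truth = truth, config = config),
            class = "sim_counts")
}

#' Simulate gene sets with optionally planted DE enrichment
#'
#' Builds `n_sets` gene sets of `set_size` members over the simulated
#' gene universe. The first `n_enriched` sets are planted as enriched:
#' their members are sampled without replacement with the probability
#' weight of every DE gene multiplied by `enrichment_rho`, so the odds
#' that a member is DE is inflated by roughly that factor. The remaining
#' sets sample genes uniformly. Enriched sets are flagged
#' `"immunological"` (the label the off-target screen watches), the
#' rest `"other"`.
#'
#' @param config the [sim_config()] used for [simulate_counts()].
#' @param truth the `truth` element returned by [simulate_counts()].
#' @return A [gene_set_collection()] whose `flags` mark the planted
#'   sets; the names of planted sets are also in
#'   `attr(collection, "enriched_sets")`.
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (config$set_size > config$n_genes)
    stop("invalid sim_config field 'set_size': must not exceed n_genes")
  set.seed(config$seed + 1L)
  universe <- names(truth$signed_log2fc)
  is_de <- universe %in% truth$de_genes
  n_sets <- config$n_sets
  if (n_sets == 0L)
    return(gene_set_collection(list(), universe = universe))

  enriched <- seq_len(n_sets) <= config$n_enriched
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  w_enriched <- ifelse(is_de, config$enrichment_rho, 1)
  for (k in seq_len(n_sets)) {
    sets[[k]] <- if (enriched[k])
      sample(universe, config$set_size, prob = w_enriched)
    else
      sample(universe, config$set_size)
  }
  flags <- stats::setNames(ifelse(enriched, "immunological", "other"),
                           names(sets))
  coll <- gene_set_collection(sets, universe = universe, flags = flags)
  attr(coll, "enriched_sets") <- names(sets)[enriched]
  coll
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates cycle-threshold (Ct) values for one target and one
#' reference gene across `n_samples` samples, with sample 1 as the
#' calibrator. Fold changes relative to the calibrator are planted
#' exactly by construction (`Ct_target = Ct_ref + dCt_cal -
#' log2(fold)`), so [ddct_fold_change()] recovers them by inverting the
#' 2^-ddCt formula; optional Gaussian technical noise can be added per
#' Ct value.
#'
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed.
#' @param fold optional numeric vector of planted fold changes, one per
#'   sample (the calibrator's entry is forced to 1). Default: all 1.
#' @param noise_sd standard deviation (cycles) of technical noise added
#'   to each Ct value; default 0 gives exact recovery.
#' @return A data.frame of class `"ct_table"` with columns `sample`,
#'   `ct_target`, `ct_reference`, attribute `calibrator`, and the
#'   planted folds in `attr(, "planted_fold")`.
#' @export
simulate_ct_table <- function(n_samples, seed = 1L, fold = NULL,
                              noise_sd = 0) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("'n_samples' must be >= 1")
  n_samples <- as.integer(n_samples)
  if (is.null(fold)) fold <- rep(1, n_samples)
  if (length(fold) != n_samples)
    stop("'fold' must have one entry per sample")
  set.seed(as.integer(seed))
  fold[1L] <- 1
  ct_ref <- stats::runif(n_samples, 18, 22)
  dct_cal <- stats::runif(1, 3, 8)        # target expressed below reference
  ct_target <- ct_ref + dct_cal - log2(fold)
  if (noise_sd > 0) {
    ct_target <- ct_target + stats::rnorm(n_samples, 0, noise_sd)
    ct_ref <- ct_ref + stats::rnorm(n_samples, 0, noise_sd)
  }
  if (any(ct_target < 15 | ct_target > 35))
    warning("planted folds push some target Ct values outside 15-35 cycles")
  out <- data.frame(sample = sprintf("sample_%d", seq_len(n_samples)),
                    ct_target = ct_target, ct_reference = ct_ref,
                    stringsAsFactors = FALSE)
  attr(out, "calibrator") <- out$sample[1L]
  attr(out, "planted_fold") <- stats::setNames(fold, out$sample)
  class(out) <- c("ct_table", "data.frame")
  out
}
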