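#' Per-gene two-sample T statistics
#'
#' Classical pooled-variance two-sample t statistics, one per gene
#' (row), for a two-group design. By default counts are transformed to
#' `log2(count + 1)`, on which a location-shift statistic is defensible
#' for sequencing counts; set `transform = "raw"` to use the counts as
#' is. Genes whose pooled variance is zero (including genes constant
#' across all samples) get statistic 0 so they can never enter a
#' putative set; alternatively `epsilon > 0` adds a stabilizing
#' constant to the pooled standard error.
#'
#' @param x a [count_matrix()] (or plain matrix, with `groups` given).
#' @param groups group labels per sample; taken from `x` when it is a
#'   `count_matrix`. Exactly two groups, each with at least two samples.
#' @param transform `"log2p1"` (default) or `"raw"`.
#' @param epsilon nonnegative stabilizer added to the pooled standard
#'   error denominator (default 0).
#' @return Named numeric vector of t statistics
#'   (`mean(group1) - mean(group2)` over the pooled standard error),
#'   finite for every gene. Group 1 is the first group label in sort
#'   order... see Details.
#'
#' @details The sign convention is `mean(first group) - mean(second
#' group)` where groups are ordered by first appearance among the
#' columns. Downstream FDR estimation uses `|t|` only, so the sign
#' convention never affects the screen.
#' @export
#' @examples
#' m <- matrix(c(10, 12, 20, 22), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' row_t_stats(m, groups = c("a", "a", "b", "b"), transform = "raw")
#' # |t| = 10 / sqrt(2)
row_t_stats <- function(x, groups = NULL,
                        transform = c("log2p1", "raw"), epsilon = 0) {
  transform <- match.arg(transform)
  if (inherits(x, "count_matrix")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$counts
  }
  if (is.null(groups)) stop("'groups' required for a plain matrix")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (variance undefined)")
  y <- if (transform == "log2p1") log2(x + 1) else x * 1.0
  if (any(!is.finite(y))) stop("non-finite values after transform")

  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  ss1 <- rowSums((y[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((y[, i2, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2)) + epsilon
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  t[!is.finite(t)] <- 0
  stats::setNames(t, rownames(x))
}

#' Enumerate balanced permutations of a two-group labeling
#'
#' All distinct relabelings of the samples that preserve the two group
#' sizes, excluding the observed labeling, with a relabeling and its
#' group-name swap counted once when the design is balanced. For the
#' 2-vs-2 design this yields exactly the two "mixed" partitions that
#' pair one sample of each original group — e.g. for samples
#' `T1,T2,C1,C2`: `{T1,C1} | {T2,C2}` and `{T1,C2} | {T2,C1}`.
#'
#' @param sample_ids character vector of sample ids.
#' @param groups named (or positional) group labels, two groups.
#' @return An object of class `"perm_scheme"`: list with `partitions`
#'   (list of named group-label vectors), `observed` (the input
#'   labeling) and `n` (number of permutations).
#' @export
#' @examples
#' sch <- balanced_permutations(c("T1", "T2", "C1", "C2"),
#'                              c("t", "t", "c", "c"))
#' sch$n  # 2
balanced_permutations <- function(sample_ids, groups) {
  groups <- as.character(groups)
  if (is.null(names(groups))) names(groups) <- sample_ids
  groups <- groups[sample_ids]
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == lev[1L])
  n <- length(sample_ids)

  idx1 <- utils::combn(n, n1, simplify = FALSE)
  balanced <- n1 == (n - n1)
  if (balanced) {
    # identify a partition with its group-name swap: keep only the
    # subsets containing sample 1
    idx1 <- Filter(function(s) 1L %in% s, idx1)
  }
  observed <- which(groups == lev[1L])
  if (balanced && !(1L %in% observed)) observed <- setdiff(seq_len(n), observed)
  partitions <- list()
  for (s in idx1) {
    if (identical(as.integer(s), as.integer(observed))) next
    lab <- rep(lev[2L], n)
    lab[s] <- lev[1L]
    partitions[[length(partitions) + 1L]] <- stats::setNames(lab, sample_ids)
  }
  if (!length(partitions))
    stop("group sizes admit no balanced relabeling other than the observed one")
  structure(list(partitions = partitions, observed = groups,
                 n = length(partitions)),
            class = "perm_scheme")
}

#' @export
print.perm_scheme <- function(x, ...) {
  cat("perm_scheme: ", x$n, " balanced relabeling(s) of ",
      length(x$observed), " samples (observed labeling excluded)\n", sep = "")
  invisible(x)
}

#' Permutation-FDR differential expression screen
#'
#' Fits the low-replicate differential-expression screen built for
#' designs with as few as two replicates per condition. Per-gene
#' two-sample T statistics are computed for the observed labeling and
#' for every balanced relabeling of the samples that mixes the groups;
#' the observed exceedance spectrum (number of genes with `|T|` at or
#' above each cutoff) is compared with the permutation-averaged
#' spectrum, giving at each cutoff `c` the estimated false discovery
#' rate
#' \deqn{\widehat{FDR}(c) = \frac{\mathrm{mean}_{perm}\,\#\{g : |T^{perm}_g| \ge c\}}{\#\{g : |T^{obs}_g| \ge c\}},}
#' clipped to `[0, 1]` and made monotone non-increasing in the cutoff
#' by the q-value envelope `q(c) = min over cutoffs c' <= c of the raw
#' ratio`. The putative set at a nominal level (default 0.5) is every
#' gene whose `|T|` reaches the least stringent cutoff with
#' `q <= level`; at level 0.5 about half of the list is expected to be
#' truly differentially expressed, which is what makes the list usable
#' for enrichment propagation (see [offtarget_screen()]).
#'
#' @param x a [count_matrix()], or a plain counts matrix with `groups`.
#' @param groups two-group labels per sample (from `x` if a
#'   `count_matrix`).
#' @param level nominal FDR level in `(0, 1]` for the putative set
#'   (default 0.5).
#' @param transform,epsilon passed to [row_t_stats()].
#' @return An object of class `"perm_fdr"`: list with `t_obs`,
#'   `scheme`, `grid` (distinct `|T|` cutoffs, descending),
#'   `obs_exceedance`, `perm_exceedance_mean`, `fdr_raw`, `fdr_curve`
#'   (monotone), `level`, `putative_set`, `transform`, `call`.
#' @seealso [extract_putative_set()], [summary.perm_fdr()],
#'   [plot.perm_fdr()]
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 500, pi1 = 0.1, seed = 3))
#' fit <- perm_fdr(sim$matrix)
#' fit
#' length(fit$putative_set)
perm_fdr <- function(x, groups = NULL, level = 0.5,
                     transform = c("log2p1", "raw"), epsilon = 0) {
  transform <- match.arg(transform)
  cl <- match.call()
  if (inherits(x, "count_matrix")) {
    if (is.null(groups)) groups <- x$groups
    counts <- x$counts
  } else {
    counts <- as.matrix(x)
    if (is.null(groups)) stop("'groups' required for a plain matrix")
    if (is.null(names(groups))) groups <- stats::setNames(as.character(groups),
                                                          colnames(counts))
  }
  if (nrow(counts) == 0L) stop("empty count matrix")
  groups <- as.character(groups[colnames(counts)])
  names(groups) <- colnames(counts)

  t_obs <- row_t_stats(counts, groups, transform = transform,
                       epsilon = epsilon)
  scheme <- balanced_permutations(colnames(counts), groups)
  t_perm <- lapply(scheme$partitions, function(lab)
    row_t_stats(counts, lab, transform = transform, epsilon = epsilon))

  res <- fdr_curve_from_spectra(t_obs, t_perm)
  fit <- structure(c(res, list(
    scheme = scheme, level = level, transform = transform,
    epsilon = epsilon, groups = groups, call = cl)), class = "perm_fdr")
  fit$putative_set <- extract_putative_set(fit, level)
  fit
}

# Observed vs permutation-averaged exceedance spectra and the FDR curve.
# t_perm: list of per-gene statistic vectors, one per permutation.
fdr_curve_from_spectra <- function(t_obs, t_perm) {
  a_obs <- sort(abs(unname(t_obs)))
  grid <- sort(unique(a_obs), decreasing = TRUE)      # descending cutoffs
  # #{|T| >= c} = n - #{|T| < c}; findInterval(c, sorted, left.open=TRUE)
  # counts values strictly below c
  exceedance <- function(sorted_abs)
    length(sorted_abs) - findInterval(grid, sorted_abs, left.open = TRUE)
  obs_exc <- exceedance(a_obs)
  pm <- vapply(t_perm, function(tp)
    exceedance(sort(abs(unname(tp)))), numeric(length(grid)))
  perm_exc <- rowMeans(matrix(pm, nrow = length(grid)))

  keep <- obs_exc > 0                                  # guard: never divides by 0
  grid <- grid[keep]; obs_exc <- obs_exc[keep]; perm_exc <- perm_exc[keep]
  raw <- pmin(pmax(perm_exc / obs_exc, 0), 1)
  # monotone non-increasing in the cutoff: q(c) = min_{c' <= c} raw(c')
  mono <- rev(cummin(rev(raw)))
  list(t_obs = t_obs,
       grid = grid,
       obs_exceedance = obs_exc,
       perm_exceedance_mean = perm_exc,
       fdr_raw = raw,
       fdr_curve = mono)
}

#' Extract the putative gene set at a nominal FDR level
#'
#' Returns every gene whose `|T|` meets the least stringent cutoff whose
#' monotone FDR estimate is at or below `level`. An empty character
#' vector is returned when no cutoff qualifies.
#'
#' @param fit a [perm_fdr()] fit.
#' @param level nominal FDR in `(0, 1]`; defaults to the fit's level.
#' @return Character vector of gene ids.
#' @export
extract_putative_set <- function(fit, level = fit$level) {
  stopifnot(inherits(fit, "perm_fdr"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1)
    stop("'level' must be in (0, 1]")
  ok <- fit$fdr_curve <= level
  if (!any(ok)) return(character(0))
  tstar <- min(fit$grid[ok])    # least stringent qualifying cutoff
  names(fit$t_obs)[abs(fit$t_obs) >= tstar]
}

#' @export
print.perm_fdr <- function(x, ...) {
  cat("Permutation-FDR differential expression screen\n")
  cat("  genes: ", length(x$t_obs), ", samples: ", length(x$groups),
      " (", paste(sprintf("%s n=%d", names(table(x$groups)),
                          as.integer(table(x$groups))), collapse = ", "),
      ")\n", sep = "")
  cat("  balanced permutations: ", x$scheme$n,
      " (observed labeling excluded)\n", sep = "")
  cat("  transform: ", x$transform, "\n", sep = "")
  cat("  putative set at FDR level ", x$level, ": ",
      length(x$putative_set), " genes\n", sep = "")
  invisible(x)
}

#' Summarize a permutation-FDR fit
#'
#' @param object a [perm_fdr()] fit.
#' @param levels FDR levels at which to report putative-set sizes.
#' @param ... unused.
#' @return An object of class `"summary.perm_fdr"` printed as a small
#'   table of level, qualifying `|T|` cutoff and list size, plus the
#'   top genes by `|T|`.
#' @export
summary.perm_fdr <- function(object, levels = c(0.1, 0.25, 0.5, 0.75),
                             ...) {
  rows <- lapply(levels, function(l) {
    genes <- extract_putative_set(object, l)
    ok <- object$fdr_curve <= l
    data.frame(level = l,
               cutoff = if (any(ok)) min(object$grid[ok]) else NA_real_,
               n_genes = length(genes))
  })
  out <- list(table = do.call(rbind, rows),
              top = utils::head(sort(abs(object$t_obs),
                                     decreasing = TRUE), 10L),
              fit = object)
  class(out) <- "summary.perm_fdr"
  out
}

#' @export
print.summary.perm_fdr <- function(x, ...) {
  print(x$fit)
  cat("\nPutative-set size by nominal FDR level:\n")
  print(x$table, row.names = FALSE)
  cat("\nTop genes by |T|:\n")
  print(round(x$top, 3))
  invisible(x)
}

#' @export
coef.perm_fdr <- function(object, ...) object$t_obs

#' Plot the estimated FDR curve of a permutation screen
#'
#' Draws the raw spectrum ratio and its monotone envelope against the
#' `|T|` cutoff, with the nominal level and the qualifying cutoff
#' marked.
#'
#' @param x a [perm_fdr()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.perm_fdr <- function(x, ...) {
  graphics::plot(x$grid, x$fdr_raw, type = "s", col = "grey60",
                 xlab = "|T| cutoff", ylab = "estimated FDR",
                 ylim = c(0, 1), ...)
  graphics::lines(x$grid, x$fdr_curve, type = "s", col = "black", lwd = 2)
  graphics::abline(h = x$level, lty = 2)
  ok <- x$fdr_curve <= x$level
  if (any(ok)) graphics::abline(v = min(x$grid[ok]), lty = 3)
  graphics::legend("topright", c("raw ratio", "monotone envelope"),
                   col = c("grey60", "black"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
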