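#' Remove rRNA-flagged genes from a count matrix
#'
#' Ribosomal RNA dominates unselected RNA-seq libraries and is removed
#' before normalization. Here rRNA genes are identified by the boolean
#' flag carried on the [count_matrix()] (sequence-level identification
#' is out of scope); flagged rows are dropped, preserving the order of
#' the remaining genes.
#'
#' @param x a `count_matrix`.
#' @return A `count_matrix` without the flagged genes. If `x` carries no
#'   flags the input is returned unchanged with a warning.
#' @export
filter_rrna <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$rrna)) {
    warning("no rRNA flags on this count matrix; returning it unchanged")
    return(x)
  }
  keep <- !x$rrna
  count_matrix(x$counts[keep, , drop = FALSE], groups = x$groups,
               rrna = x$rrna[keep])
}

#' Equalize sequencing depth by without-replacement count subsampling
#'
#' Emulates read-level depth normalization on a quantified count matrix:
#' every sample is randomly downsampled, without replacement, to the
#' smallest original column total, so that afterwards all column sums
#' are exactly equal integers. Each column is drawn from the
#' multivariate hypergeometric distribution with the gene counts as
#' category sizes — the distribution of gene labels obtained by
#' subsampling the sample's reads uniformly. A binomial thinning
#' alternative (counts kept independently with probability
#' `target/total`) is available; it preserves totals only in
#' expectation.
#'
#' @param x a `count_matrix`; every column total must be positive.
#' @param seed optional integer seed for reproducibility.
#' @param method `"hypergeometric"` (default, exact totals) or
#'   `"binomial"`.
#' @return A `count_matrix` of the same shape with every downsampled
#'   count no larger than the original.
#' @export
#' @examples
#' m <- matrix(c(60L, 40L, 30L, 20L), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' eq <- equalize_depth(count_matrix(m, c("a", "b")), seed = 1)
#' colSums(eq$counts)  # both 50
equalize_depth <- function(x, seed = NULL,
                           method = c("hypergeometric", "binomial")) {
  stopifnot(inherits(x, "count_matrix"))
  method <- match.arg(method)
  if (nrow(x$counts) == 0L)
    stop("empty count matrix: nothing to equalize")
  totals <- colSums(x$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  target <- min(totals)
  out <- x$counts
  for (j in seq_len(ncol(out))) {
    if (totals[j] == target) next
    out[, j] <- if (method == "hypergeometric")
      rmvhyper(x$counts[, j], target)
    else
      stats::rbinom(nrow(out), x$counts[, j], target / totals[j])
  }
  count_matrix(out, groups = x$groups, rrna = x$rrna)
}

# One multivariate hypergeometric draw: subsample `n` reads without
# replacement from categories with sizes `counts`, by sequential
# conditional univariate hypergeometric draws.
rmvhyper <- function(counts, n) {
  k <- length(counts)
  out <- integer(k)
  remaining <- sum(counts)
  for (i in seq_len(k)) {
    if (n == 0L) break
    ci <- counts[i]
    x <- stats::rhyper(1L, ci, remaining - ci, n)
    out[i] <- x
    n <- n - x
    remaining <- remaining - ci
  }
  out
}
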