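#' Hierarchical clustering of samples on a gene subset
#'
#' Agglomerative clustering of the samples using Euclidean distance on
#' (by default) `log2(count + 1)` expression, restricted to a gene list
#' — typically the union of the putative differentially expressed
#' genes. Linkage defaults to average (UPGMA); `stats::hclust` breaks
#' ties deterministically by merge order, so the tree is reproducible
#' for a given input.
#'
#' @param x a [count_matrix()] or numeric matrix (genes x samples).
#' @param genes optional character vector restricting the rows.
#' @param transform `"log2p1"` (default), `"raw"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class [stats::hclust].
#' @seealso [dendrogram_newick()]
#' @export
cluster_samples <- function(x, genes = NULL,
                            transform = c("log2p1", "raw"),
                            linkage = c("average", "complete", "single")) {
  transform <- match.arg(transform)
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("genes not in the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("at least two samples required")
  if (any(!is.finite(m))) stop("missing or non-finite values")
  y <- if (transform == "log2p1") log2(m + 1) else m
  stats::hclust(stats::dist(t(y), method = "euclidean"), method = linkage)
}

#' Serialize a dendrogram as Newick with branch heights
#'
#' @param hc an [stats::hclust] tree.
#' @return A single Newick string (branch lengths from merge heights).
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Venn overlap counts of two gene lists
#'
#' @param list_a,list_b character vectors (duplicates ignored).
#' @return Named integer vector `c(only_a, only_b, both)`.
#' @export
#' @examples
#' venn_counts(c("a", "b", "c"), c("b", "c", "d"))
venn_counts <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, only_b = length(b) - both, both = both)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Standard qPCR relative quantification: for each sample
#' `fold = 2^-((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator)`.
#' The calibrator's own fold is exactly 1. The quantity is invariant to
#' any Ct shift applied equally to target and reference of a sample
#' (loading differences cancel).
#'
#' @param ct a `ct_table` (see [simulate_ct_table()]) or data.frame
#'   with columns `sample`, `ct_target`, `ct_reference`.
#' @param calibrator sample id of the calibrator; defaults to the
#'   table's `calibrator` attribute.
#' @return Named numeric vector of fold changes per sample.
#' @export
ddct_fold_change <- function(ct, calibrator = NULL) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "ct_target", "ct_reference") %in% names(ct)))
  if (anyNA(ct$ct_reference) || anyNA(ct$ct_target))
    stop("missing Ct value(s)")
  if (is.null(calibrator)) calibrator <- attr(ct, "calibrator")
  if (is.null(calibrator) || !calibrator %in% ct$sample)
    stop("calibrator sample not found in the table")
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - dct[ct$sample == calibrator]
  stats::setNames(2^(-ddct), ct$sample)
}
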