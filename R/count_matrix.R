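#' Construct a labeled count matrix
#'
#' Bundles an integer gene-by-sample count matrix with the sample group
#' labels and an optional per-gene rRNA flag. This is the container every
#' analysis step in the package consumes and returns.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Must
#'   have unique non-empty row and column names.
#' @param groups character (or factor) vector of group labels, one per
#'   sample. Either named by sample id or in column order.
#' @param rrna optional logical vector, one per gene, flagging ribosomal
#'   RNA genes for removal by [filter_rrna()]. Either named by gene id or
#'   in row order.
#'
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (integer matrix), `groups` (named character) and `rrna`
#'   (named logical or `NULL`).
#' @seealso [read_counts()], [filter_rrna()], [equalize_depth()],
#'   [perm_fdr()]
#' @export
#' @examples
#' m <- matrix(rpois(40, 20), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' cm <- count_matrix(m, groups = c("treated", "treated", "control", "control"))
#' cm
count_matrix <- function(counts, groups, rrna = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) > 0L && is.null(rownames(counts)))
    stop("'counts' must have gene row names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts)))
    stop("'counts' must have sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in 'counts'")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("'counts' must be integers")
  storage.mode(counts) <- "integer"

  nm <- names(groups)
  groups <- as.character(groups)
  names(groups) <- nm
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("'groups' must have one label per sample")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(counts)]

  if (!is.null(rrna)) {
    if (is.null(names(rrna))) {
      if (length(rrna) != nrow(counts))
        stop("'rrna' must have one flag per gene")
      names(rrna) <- rownames(counts)
    }
    rrna <- as.logical(rrna)[match(rownames(counts), names(rrna))]
    names(rrna) <- rownames(counts)
    if (anyNA(rrna)) stop("'rrna' flags missing for some genes")
  }

  structure(list(counts = counts, groups = groups, rrna = rrna),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$rrna))
    cat("rRNA-flagged genes: ", sum(x$rrna), "\n", sep = "")
  cat("column totals: ",
      paste(colSums(x$counts), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x a `count_matrix`.
#' @param i gene ids or indices (rows).
#' @param j sample ids or indices (columns).
#' @param ... unused.
#' @return A `count_matrix` restricted to the requested rows/columns.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               groups = x$groups[j],
               rrna = if (is.null(x$rrna)) NULL else x$rrna[i])
}
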