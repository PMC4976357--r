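#' Read and write count matrices as delimited text
#'
#' Counts are stored as tab-delimited text with gene ids in the first
#' column and a header row of sample ids; group labels live in a separate
#' two-column samples file (`sample_id`, `group`). rRNA flags, when
#' present, are stored as an extra `rrna` column (0/1) appended to the
#' counts table.
#'
#' @param counts_file path of the tab-delimited counts table.
#' @param samples_file path of the two-column samples table.
#' @param x a [count_matrix()] to write.
#' @return `read_counts()` returns a `count_matrix`; the writers return
#'   the input invisibly.
#' @export
read_counts <- function(counts_file, samples_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  tab <- tab[-1L]
  rrna <- NULL
  if ("rrna" %in% names(tab)) {
    rrna <- as.logical(as.integer(tab[["rrna"]]))
    names(rrna) <- gene_ids
    tab <- tab[setdiff(names(tab), "rrna")]
  }
  counts <- as.matrix(tab)
  rownames(counts) <- gene_ids
  samp <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(samp[[2L]]), as.character(samp[[1L]]))
  count_matrix(counts, groups = groups, rrna = rrna)
}

#' @rdname read_counts
#' @export
write_counts <- function(x, counts_file, samples_file) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  if (!is.null(x$rrna)) tab$rrna <- as.integer(x$rrna)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  samp <- data.frame(sample_id = names(x$groups), group = unname(x$groups))
  utils::write.table(samp, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read and write gene-set collections in GMT format
#'
#' One set per line: set name, description, then tab-separated member
#' gene ids. On reading, the universe defaults to the union of all
#' members unless supplied.
#'
#' @param path GMT file path.
#' @param universe optional character vector of gene ids forming the
#'   background universe.
#' @param collection a `gene_set_collection` (see
#'   [simulate_gene_sets()]) to write.
#' @return `read_gmt()` returns a `gene_set_collection`; `write_gmt()`
#'   returns its input invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (is.null(universe)) universe <- unique(unlist(sets))
  # the GMT description column doubles as the set flag ("na" = none)
  flags <- vapply(parts, `[[`, character(1), 2L)
  flags[flags == "na"] <- NA_character_
  names(flags) <- names(sets)
  gene_set_collection(sets, universe = universe, flags = flags)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$flags[nm]
    if (is.na(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector: the background gene universe.
#' @param flags optional named character vector of labels per set
#'   (e.g. `"immunological"`), used by [offtarget_screen()].
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe, flags = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  universe <- unique(as.character(universe))
  for (nm in names(sets)) {
    out <- setdiff(sets[[nm]], universe)
    if (length(out))
      stop("set '", nm, "' contains genes outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }
  if (is.null(flags)) {
    flags <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  } else {
    flags <- flags[names(sets)]
    names(flags) <- names(sets)
  }
  structure(list(sets = sets, universe = universe, flags = flags),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x$sets), " sets over ",
      length(x$universe), " genes\n", sep = "")
  fl <- x$flags[!is.na(x$flags)]
  if (length(fl)) {
    tab <- table(fl)
    cat("flags: ", paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
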