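#' Hypergeometric over-representation of one gene set
#'
#' One-sided (upper tail) hypergeometric test of whether a gene list
#' overlaps a set more than expected when drawing the list uniformly
#' from the universe — the standard open replacement for knowledge-base
#' enrichment tests. The p-value is exact:
#' `P(X >= k)` for `X ~ Hypergeometric(universe, set, list)`.
#'
#' @param gene_list character vector of genes (the query list); must be
#'   a subset of `universe`.
#' @param gene_set character vector of set members; must be a subset of
#'   `universe`.
#' @param universe character vector: the background gene universe.
#' @return One-row data.frame: `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p_value`, `odds_ratio` (sample odds ratio of the
#'   2x2 table; may be `Inf`).
#' @export
#' @examples
#' u <- paste0("g", 1:100)
#' fisher_enrichment(u[1:10], u[1:20], u)
fisher_enrichment <- function(gene_list, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(as.character(gene_list))
  gene_set <- unique(as.character(gene_set))
  out <- setdiff(gene_list, universe)
  if (length(out))
    stop("gene list not contained in universe: ",
         paste(utils::head(out, 10), collapse = ", "))
  out <- setdiff(gene_set, universe)
  if (length(out))
    stop("gene set not contained in universe: ",
         paste(utils::head(out, 10), collapse = ", "))

  N <- length(universe); K <- length(gene_set); n <- length(gene_list)
  k <- length(intersect(gene_list, gene_set))
  # upper tail P(X >= k), exact
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  data.frame(overlap = k, set_size = K, list_size = n, universe_size = N,
             p_value = p, odds_ratio = or)
}

#' Enrichment of a gene list against every set in a collection
#'
#' Runs [fisher_enrichment()] for each set of a
#' [gene_set_collection()] against the same list and universe, and
#' flags sets passing the fixed significance threshold. Following the
#' screening logic this package implements, the threshold is applied to
#' raw p-values by default (a deliberately liberal criterion — the
#' screen's argument needs sensitivity, not family-wise control); a
#' Benjamini-Hochberg adjustment is available as an option.
#'
#' @param gene_list character vector of query genes (subset of the
#'   collection's universe).
#' @param collection a `gene_set_collection`.
#' @param alpha significance threshold on the (possibly adjusted)
#'   p-value; default `1e-4`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of class `"enrichment_result"`, one row per
#'   set: `set`, `flag`, the [fisher_enrichment()] columns, `p_adj`,
#'   and logical `significant`; ordered by p-value. `alpha` and
#'   `adjust` are carried as attributes.
#' @export
enrich_collection <- function(gene_list, collection, alpha = 1e-4,
                              adjust = c("none", "BH")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  adjust <- match.arg(adjust)
  if (!length(collection$sets)) {
    res <- data.frame(set = character(0), flag = character(0),
                      overlap = integer(0), set_size = integer(0),
                      list_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant = logical(0))
  } else {
    rows <- lapply(names(collection$sets), function(nm)
      cbind(data.frame(set = nm, flag = unname(collection$flags[nm]),
                       stringsAsFactors = FALSE),
            fisher_enrichment(gene_list, collection$sets[[nm]],
                              collection$universe)))
    res <- do.call(rbind, rows)
    res$p_adj <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH")
                 else res$p_value
    res$significant <- res$p_adj < alpha
    res <- res[order(res$p_value), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "alpha") <- alpha
  attr(res, "adjust") <- adjust
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Expected set overlap of a diluted DE list
#'
#' The propagation argument behind screening with a liberal putative
#' list: if a fraction `pi_list` of the list is truly differentially
#' expressed and the rest is background, the expected rate at which
#' list members fall inside a given set is the mixture
#' `pi_list * de_rate + (1 - pi_list) * background_rate`. When the set
#' is enriched among true DE genes (`de_rate > background_rate`) the
#' mixture stays above background for any `pi_list > 0`, so enrichment
#' present among DE genes propagates into the putative list and remains
#' detectable.
#'
#' @param pi_list fraction of the list that is truly DE, in `(0, 1]`.
#' @param de_rate probability that a true-DE list member lies in the
#'   set, in `[0, 1]`.
#' @param background_rate probability that a background (false
#'   positive) list member lies in the set, in `[0, 1]`.
#' @return The expected overlap rate (scalar in `[0, 1]`).
#' @export
#' @examples
#' propagate_expectation(0.5, de_rate = 0.10, background_rate = 0.02)  # 0.06
propagate_expectation <- function(pi_list, de_rate, background_rate) {
  if (!is.numeric(pi_list) || pi_list <= 0 || pi_list > 1)
    stop("'pi_list' must be in (0, 1]")
  for (r in c(de_rate, background_rate))
    if (!is.numeric(r) || r < 0 || r > 1)
      stop("rates must be in [0, 1]")
  pi_list * de_rate + (1 - pi_list) * background_rate
}

#' Off-target screening verdict from enrichment results
#'
#' Partitions the significant sets of an [enrich_collection()] result
#' by their flag and reports whether any set carrying the watched flag
#' (immunological pathways, by default) is significant. The screen is
#' "clean" exactly when none is: the logic being that a genuine
#' immune-directed off-target effect of the edit would leave
#' immune-flagged sets enriched among the differentially expressed
#' genes, and hence — by propagation — significant on the putative
#' list.
#'
#' @param results an `enrichment_result` (or compatible data.frame with
#'   columns `set`, `flag`, `p_value`).
#' @param alpha significance threshold on raw p-values; defaults to the
#'   result's own alpha (or `1e-4`).
#' @param watch_flag flag treated as the off-target signal; default
#'   `"immunological"`.
#' @return An object of class `"offtarget_verdict"`: list with `clean`
#'   (logical), `significant_watched`, `significant_other` (character
#'   vectors of set names), `alpha`, `watch_flag`.
#' @export
offtarget_screen <- function(results, alpha = NULL,
                             watch_flag = "immunological") {
  stopifnot(is.data.frame(results),
            all(c("set", "flag", "p_value") %in% names(results)))
  if (anyNA(results$flag))
    stop("every set needs a flag; missing for: ",
         paste(results$set[is.na(results$flag)], collapse = ", "))
  if (is.null(alpha)) alpha <- attr(results, "alpha")
  if (is.null(alpha)) alpha <- 1e-4
  sig <- results$p_value < alpha
  watched <- results$flag == watch_flag
  structure(list(clean = !any(sig & watched),
                 significant_watched = results$set[sig & watched],
                 significant_other = results$set[sig & !watched],
                 alpha = alpha, watch_flag = watch_flag),
            class = "offtarget_verdict")
}

#' @export
print.offtarget_verdict <- function(x, ...) {
  cat("Off-target enrichment screen (alpha = ",
      format(x$alpha), ", watched flag: ", x$watch_flag, ")\n", sep = "")
  cat(if (x$clean) "VERDICT: clean - no watched set significant\n"
      else paste0("VERDICT: NOT clean - significant watched set(s): ",
                  paste(x$significant_watched, collapse = ", "), "\n"))
  if (length(x$significant_other))
    cat("other significant sets: ",
        paste(x$significant_other, collapse = ", "), "\n", sep = "")
  invisible(x)
}
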