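#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case kept
#'   uppercase).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GATTACA")
revcomp <- function(x) {
  x <- toupper(as.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct an amplicon with annotated SNPs
#'
#' An amplicon is the genomic reference fragment targeted by the edit,
#' annotated with the single-nucleotide polymorphisms whose alleles the
#' repair template will carry. Coordinates are 0-based half-open
#' throughout; SNP labels are display strings only (e.g. promoter-
#' relative aliases like `-251` alongside rs numbers).
#'
#' @param sequence DNA string (A/C/G/T; uppercased).
#' @param snps data.frame with columns `pos` (0-based), `ref`, `alt`,
#'   `label`; positions must be strictly increasing and each `ref`
#'   allele must match the sequence.
#' @return An object of class `"amplicon"`.
#' @export
amplicon <- function(sequence, snps) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    bad <- regexpr("[^ACGT]", sequence)
    stop("non-ACGT character at position ", bad - 1L, " (0-based)")
  }
  stopifnot(is.data.frame(snps),
            all(c("pos", "ref", "alt", "label") %in% names(snps)))
  snps$pos <- as.integer(snps$pos)
  if (is.unsorted(snps$pos, strictly = TRUE))
    stop("SNP positions must be strictly increasing")
  if (any(snps$pos < 0 | snps$pos >= nchar(sequence)))
    stop("SNP position outside the amplicon")
  at <- substring(sequence, snps$pos + 1L, snps$pos + 1L)
  bad <- which(at != toupper(snps$ref))
  if (length(bad))
    stop("reference allele mismatch at SNP ", snps$label[bad[1L]],
         ": sequence has ", at[bad[1L]], ", ref given as ", snps$ref[bad[1L]])
  structure(list(sequence = sequence, snps = snps), class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("amplicon: ", nchar(x$sequence), " bp, ", nrow(x$snps),
      " SNP(s): ", paste(x$snps$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an amplicon from FASTA plus a SNP table
#'
#' @param fasta_file FASTA file containing one sequence.
#' @param snps_file tab-delimited file with columns `pos`, `ref`,
#'   `alt`, `label` (0-based positions).
#' @return An [amplicon()].
#' @export
read_amplicon <- function(fasta_file, snps_file) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record")
  snps <- utils::read.delim(snps_file, stringsAsFactors = FALSE)
  amplicon(as.character(seqs[[1L]]), snps)
}

#' Scan an amplicon for SpCas9 PAM sites
#'
#' Finds every NGG protospacer-adjacent motif on both strands that
#' leaves room for a full protospacer immediately 5' of the PAM (on the
#' PAM's strand), and returns one candidate guide per site. The blunt
#' SpCas9 cut is placed 3 bp 5' of the PAM (between protospacer
#' positions 17 and 18 of the 20-mer convention); `cut_site` is the
#' 0-based boundary coordinate of that cut on the forward strand.
#'
#' @param x an [amplicon()] or a plain DNA string.
#' @param protospacer_len protospacer length (default 20; the guide
#'   inserts this package was designed around carry 23-nt
#'   protospacers).
#' @return data.frame with one row per candidate: `protospacer`,
#'   `strand` (`"+"`/`"-"`), `proto_start`, `proto_end`, `pam_start`,
#'   `pam_end` (all 0-based half-open on the forward strand), `pam`,
#'   `cut_site`.
#' @export
#' @examples
#' scan_pams("ACGTAGGCGG", protospacer_len = 2)
scan_pams <- function(x, protospacer_len = 20L) {
  seq <- if (inherits(x, "amplicon")) x$sequence else toupper(as.character(x))
  if (grepl("[^ACGT]", seq))
    stop("non-ACGT character at position ",
         regexpr("[^ACGT]", seq) - 1L, " (0-based)")
  L <- as.integer(protospacer_len)
  n <- nchar(seq)
  if (n < L + 3L) stop("sequence shorter than protospacer + PAM")
  chars <- strsplit(seq, "")[[1L]]

  rows <- list()
  # forward: PAM = NGG at [p, p+3), protospacer at [p-L, p);
  # indices below are 1-based positions of the PAM's N
  pam_fwd <- which(chars[-c(1L, n)] == "G" & chars[-(1:2)] == "G")
  for (p in pam_fwd) {            # p is 1-based index of N
    p0 <- p - 1L                  # 0-based PAM start
    if (p0 - L < 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = substr(seq, p0 - L + 1L, p0),
      strand = "+", proto_start = p0 - L, proto_end = p0,
      pam_start = p0, pam_end = p0 + 3L,
      pam = substr(seq, p0 + 1L, p0 + 3L),
      cut_site = p0 - 3L, stringsAsFactors = FALSE)
  }
  # reverse: PAM appears as CCN at [p, p+3) on the forward strand,
  # protospacer at [p+3, p+3+L)
  pam_rev <- which(chars[-c(n - 1L, n)] == "C" & chars[-c(1L, n)] == "C")
  for (p in pam_rev) {            # p is 1-based index of first C
    p0 <- p - 1L
    if (p0 + 3L + L > n) next
    proto_fwd <- substr(seq, p0 + 4L, p0 + 3L + L)
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = revcomp(proto_fwd),
      strand = "-", proto_start = p0 + 3L, proto_end = p0 + 3L + L,
      pam_start = p0, pam_end = p0 + 3L,
      pam = revcomp(substr(seq, p0 + 1L, p0 + 3L)),
      cut_site = p0 + 6L, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protospacer = character(0), strand = character(0),
                      proto_start = integer(0), proto_end = integer(0),
                      pam_start = integer(0), pam_end = integer(0),
                      pam = character(0), cut_site = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

#' Select guide pairs flanking the first and third SNP
#'
#' Implements the pair-selection constraint used for excision-and-
#' repair editing of a three-SNP haplotype block: the first guide must
#' cut strictly downstream of (greater coordinate than) the first SNP
#' and the second guide strictly upstream of (smaller coordinate than)
#' the third SNP, with the first cut before the second. Returned pairs
#' are ranked with those whose excised interval contains the middle SNP
#' first, longer excised intervals breaking ties first.
#'
#' @param candidates candidate table from [scan_pams()].
#' @param snps SNP data.frame (`pos`, `ref`, `alt`, `label`) with at
#'   least three rows in increasing position order, or an [amplicon()].
#' @return data.frame of qualifying pairs: `g1`, `g2` (row indices into
#'   `candidates`), `cut1`, `cut2`, `excised_len`, `covers_mid`,
#'   protospacers of both guides. Empty (with a warning) when no pair
#'   qualifies.
#' @export
select_flanking_pairs <- function(candidates, snps) {
  if (inherits(snps, "amplicon")) snps <- snps$snps
  if (nrow(snps) < 3L) stop("at least three ordered SNPs required")
  if (!nrow(candidates)) stop("no candidate guides supplied")
  s1 <- snps$pos[1L]; s2 <- snps$pos[2L]; s3 <- snps$pos[3L]
  cut <- candidates$cut_site
  ok1 <- which(cut > s1)
  ok2 <- which(cut < s3)
  pairs <- expand.grid(g1 = ok1, g2 = ok2)
  pairs <- pairs[cut[pairs$g1] < cut[pairs$g2], , drop = FALSE]
  if (!nrow(pairs)) {
    warning("no guide pair satisfies the flanking constraints")
    return(data.frame(g1 = integer(0), g2 = integer(0), cut1 = integer(0),
                      cut2 = integer(0), excised_len = integer(0),
                      covers_mid = logical(0), protospacer1 = character(0),
                      protospacer2 = character(0)))
  }
  out <- data.frame(
    g1 = pairs$g1, g2 = pairs$g2,
    cut1 = cut[pairs$g1], cut2 = cut[pairs$g2],
    excised_len = cut[pairs$g2] - cut[pairs$g1],
    covers_mid = cut[pairs$g1] <= s2 & s2 < cut[pairs$g2],
    protospacer1 = candidates$protospacer[pairs$g1],
    protospacer2 = candidates$protospacer[pairs$g2],
    stringsAsFactors = FALSE)
  out <- out[order(-out$covers_mid, -out$excised_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build Golden-Gate cloning oligos for a protospacer
#'
#' Constructs the complementary oligo pair that, once annealed, carries
#' the 4-nt 5' overhangs matching a BbsI-digested sgRNA expression
#' vector: forward = `CACC` + protospacer, reverse = `AAAC` +
#' reverse-complement(protospacer). Stripping the adapters, the reverse
#' oligo is the exact reverse complement of the forward one. An
#' optional leading `G` (sometimes added for U6 transcription when the
#' protospacer does not start with G) can be requested; it is off by
#' default.
#'
#' @param protospacer DNA string (non-empty).
#' @param g_prepend prepend `G` to the protospacer on the forward oligo
#'   (and a matching trailing `C` on the reverse)? Default `FALSE`.
#' @return An object of class `"oligo_pair"`: list with `forward`,
#'   `reverse`, `protospacer`.
#' @export
#' @examples
#' build_insert_oligos("CCACTCTAGTACTATATCTGTCA")
build_insert_oligos <- function(protospacer, g_prepend = FALSE) {
  protospacer <- toupper(as.character(protospacer))
  if (!nchar(protospacer)) stop("empty protospacer")
  if (grepl("[^ACGT]", protospacer)) stop("protospacer must be A/C/G/T")
  core <- if (g_prepend && substr(protospacer, 1, 1) != "G")
    paste0("G", protospacer) else protospacer
  structure(list(forward = paste0("CACC", core),
                 reverse = paste0("AAAC", revcomp(core)),
                 protospacer = protospacer),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("oligo_pair (BbsI Golden-Gate adapters)\n")
  cat("  forward 5'-", x$forward, "-3' (", nchar(x$forward), " nt)\n", sep = "")
  cat("  reverse 5'-", x$reverse, "-3' (", nchar(x$reverse), " nt)\n", sep = "")
  invisible(x)
}

#' Build a homology-directed repair template carrying a haplotype
#'
#' Substitutes the requested allele at every SNP of the amplicon,
#' leaving all other positions untouched; the template length equals
#' the amplicon length. Each requested allele must be the reference or
#' the alternate allele recorded for that SNP.
#'
#' @param amp an [amplicon()].
#' @param alleles character vector of alleles, one per SNP in order
#'   (or named by SNP label).
#' @return DNA string of the repair template.
#' @export
#' @examples
#' snps <- data.frame(pos = c(2, 5), ref = c("G", "C"), alt = c("A", "T"),
#'                    label = c("snp1", "snp2"))
#' amp <- amplicon("ACGTACGT", snps)
#' build_hdr_template(amp, c("A", "T"))
build_hdr_template <- function(amp, alleles) {
  stopifnot(inherits(amp, "amplicon"))
  snps <- amp$snps
  alleles <- toupper(as.character(alleles))
  if (!is.null(names(alleles))) alleles <- alleles[snps$label]
  if (length(alleles) != nrow(snps) || anyNA(alleles))
    stop("one allele required per SNP (", nrow(snps), ")")
  seq <- amp$sequence
  for (i in seq_len(nrow(snps))) {
    a <- alleles[i]
    if (!a %in% toupper(c(snps$ref[i], snps$alt[i])))
      stop("allele ", a, " at SNP ", snps$label[i],
           " is neither ref (", snps$ref[i], ") nor alt (", snps$alt[i], ")")
    substr(seq, snps$pos[i] + 1L, snps$pos[i] + 1L) <- a
  }
  seq
}
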