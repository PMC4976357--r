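# Small fixtures shared across test files; everything is built in code.

# A count matrix from a plain integer matrix with 2-vs-2 labels.
cm_2v2 <- function(m, genes = sprintf("g%d", seq_len(nrow(m)))) {
  dimnames(m) <- list(genes, c("T1", "T2", "C1", "C2"))
  count_matrix(m, groups = c("treated", "treated", "control", "control"))
}

# Independent straight-line recomputation of the permutation FDR curve
# for a 2-vs-2 instance: explicit loops, explicit enumeration of the two
# mixed partitions, no shared code with the package internals.
brute_force_fdr <- function(counts, transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  y <- if (transform == "log2p1") log2(counts + 1) else counts
  tstat <- function(g1, g2) {
    v <- numeric(nrow(y))
    for (i in seq_len(nrow(y))) {
      a <- y[i, g1]; b <- y[i, g2]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 2
      se <- sqrt(sp2)                       # sp2 * (1/2 + 1/2)
      v[i] <- if (se > 0) (mean(a) - mean(b)) / se else 0
    }
    v
  }
  t_obs <- tstat(c(1, 2), c(3, 4))
  perms <- list(list(c(1, 3), c(2, 4)), list(c(1, 4), c(2, 3)))
  t_perm <- lapply(perms, function(p) tstat(p[[1]], p[[2]]))
  grid <- sort(unique(abs(t_obs)), decreasing = TRUE)
  raw <- numeric(length(grid))
  for (j in seq_along(grid)) {
    obs <- sum(abs(t_obs) >= grid[j])
    pm <- mean(sapply(t_perm, function(tp) sum(abs(tp) >= grid[j])))
    raw[j] <- min(1, pm / obs)
  }
  mono <- raw
  for (j in rev(seq_along(grid))[-1]) mono[j] <- min(mono[j], mono[j + 1])
  list(t_obs = t_obs, grid = grid, raw = raw, curve = mono)
}

# Toy amplicon with three SNPs and a guaranteed guide pair between
# SNP1 and SNP3 (PAMs placed by hand).
toy_amplicon <- function() {
  # layout (0-based): SNP1 at 10, SNP2 at 40, SNP3 at 70, length 90
  seq <- strrep("A", 90)
  substr(seq, 11, 11) <- "T"   # SNP1 ref T
  substr(seq, 41, 41) <- "G"   # SNP2 ref G
  substr(seq, 71, 71) <- "C"   # SNP3 ref C
  # forward PAM (TGG) with N at 0-based 30 -> cut boundary 27 (> 10)
  substr(seq, 31, 33) <- "TGG"
  # forward PAM (AGG) with N at 0-based 60 -> cut boundary 57 (< 70)
  substr(seq, 61, 63) <- "AGG"
  snps <- data.frame(pos = c(10L, 40L, 70L),
                     ref = c("T", "G", "C"), alt = c("A", "T", "T"),
                     label = c("snp-251", "snp+396", "snp+781"),
                     stringsAsFactors = FALSE)
  amplicon(seq, snps)
}
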