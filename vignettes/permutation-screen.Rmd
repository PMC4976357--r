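---
title: "Screening low-replicate RNA-seq for off-target effects: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening low-replicate RNA-seq for off-target effects: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permscreen)
```

# The statistical problem

A CRISPR-edited cell line and its unedited control are sequenced with
two RNA-seq replicates each. The question is not "which genes are
differentially expressed" — with n = 2 per group no per-gene test has
useful power at any defensible FDR — but the coarser screening question:
*is any pathway of a watched class (here, immunological pathways)
transcriptionally perturbed?* This vignette explains the model behind
`perm_fdr()` and the design decisions taken where the procedure leaves
genuine freedom.

# The permutation screen

## Statistic

For gene $g$ with transformed expression $y_{gj}$, groups of sizes
$n_1, n_2$:

$$T_g = \frac{\bar y_{g1} - \bar y_{g2}}
            {\sqrt{s_p^2\,(1/n_1 + 1/n_2)}},\qquad
  s_p^2 = \frac{\sum_1 (y - \bar y_1)^2 + \sum_2 (y - \bar y_2)^2}
               {n_1 + n_2 - 2}.$$

The transform is `log2(count + 1)` by default: a location-shift
statistic on raw counts would be dominated by the highest-expressed
genes, while log counts make the pooled-variance assumption tolerable
across the expression range. `transform = "raw"` is available. A gene
with zero pooled variance gets $T_g = 0$ — it can never enter a
putative set, which is the conservative choice for constant or
all-zero genes. An `epsilon` option adds a stabilizing constant to the
denominator; it defaults to 0 because with two permutations the ratio
estimator, not variance moderation, dominates behavior.

## The balanced mixed-permutation null

A relabeling of the samples is *balanced* if it preserves the two group
sizes. `balanced_permutations()` enumerates all of them, excluding the
observed labeling and identifying a relabeling with its group-name swap
when the design is balanced (swapping the names of both groups changes
no $|T_g|$). For the 2-vs-2 design exactly two relabelings remain — the
two ways of pairing one treated with one control sample — and each
mixes treatment and control within both groups, so treatment signal
cancels in expectation while replicate-level noise is preserved. For a
3-vs-3 design the scheme has $\binom{6}{3}/2 - 1 = 9$ members.

## Spectrum-ratio FDR and the monotone envelope

With observed statistics $T^{obs}$ and permuted statistics $T^{(p)}$,
the estimated FDR at cutoff $c$ is the ratio of the
permutation-averaged exceedance count to the observed exceedance count
(both on $|T|$; the screen is two-sided), clipped to $[0,1]$. The grid
of cutoffs is the set of distinct observed $|T|$ values, so the
denominator is never zero.

With only two permutations the raw ratio is noisy and need not be
monotone in $c$, which would make "the list at level $\alpha$"
ill-defined. We therefore report the envelope

$$q(c) = \min_{c' \le c} \widehat{FDR}(c'),$$

the standard q-value construction: the best achievable FDR among all
thresholds that still include a gene with $|T| = c$. This is the unique
direction of enforcement that makes $q$ non-increasing in the cutoff
and the putative set well-defined as *all genes at or above the least
stringent qualifying cutoff*.

## The putative set and the propagation argument

At the deliberately liberal level $0.5$, roughly half the extracted
list is expected to be truly differentially expressed. The screen's
logic does not need to know *which* half: if the truly DE genes are
pathway-enriched, and the true-DE half of the list is approximately a
random sample of all DE genes, then the list's expected overlap rate
with a set is the mixture

$$r_{list} = \pi_{list}\, r_{DE} + (1 - \pi_{list})\, r_{bg}$$

(`propagate_expectation()`), which stays above background whenever
$r_{DE} > r_{bg}$. Enrichment among DE genes therefore propagates into
the putative list and remains detectable by an ordinary one-sided
hypergeometric test (`fisher_enrichment()`; `stats::phyper` under the
surface). The screen verdict (`offtarget_screen()`) applies a fixed
raw-p threshold of $10^{-4}$ per set, with no multiplicity correction
by default: the argument needs *sensitivity* — a liberal criterion
strengthens, not weakens, a clean verdict — and a Benjamini–Hochberg
option exists for users who want the opposite guarantee.

# The synthetic data generator

The generator (`sim_config()`, `simulate_counts()`) encodes the study
conditions the screen is designed for and provides the ground truth
that the calibration tests measure against.

* **Design**: two groups (`treated`/`control`), `n_per_group = 2`.
* **Counts**: negative binomial with
  $\mathrm{Var} = \mu + \phi\mu^2$, $\phi = 0.1$ — the field-standard
  count model, chosen because the procedure itself assumes none and NB
  gives a testable mean–variance law.
* **Gene means**: log-normal, `meanlog = log(100)`, `sdlog = 1.5` — a
  median of ~100 counts with a realistically heavy right tail for a
  desk-scale library.
* **Transcriptome size**: `n_genes = 10000` by default. The real
  experiment quantified ~35,000 transcripts; 10,000 keeps a 200-seed
  calibration run in tens of seconds while leaving all rates
  (DE fraction, set sizes) in realistic proportion.
* **Planted effects**: a Bernoulli(`pi1 = 0.1`) draw marks DE genes;
  each gets log2 fold change $\pm 2$ (random sign), applied
  symmetrically ($\mu\,2^{\pm 1}$ per group) so the overall expression
  distribution is unchanged. A fixed magnitude rather than an effect
  distribution keeps "truly DE" unambiguous for calibration.
* **Library sizes**: log-normal factors with CV 0.1, mean 1 — typical
  residual depth variation, and what `equalize_depth()` removes.
* **Gene sets**: `n_sets = 50` sets of 100 genes. Enriched sets sample
  members with DE odds multiplied by `enrichment_rho`. The
  configuration has an `n_enriched` field (default: one set when
  $\rho > 1$) because the membership model needs to know *how many*
  sets are planted; planted sets are flagged `immunological` so the
  screen's watched class is exercised.
* **rRNA**: a per-gene boolean flag (default 5% of genes) rather than
  any sequence-level identification — the filter stage is exercised
  without pretending to do alignment.
* **qPCR tables**: `simulate_ct_table()` plants fold changes exactly
  (noise is opt-in via `noise_sd`), so inverting the
  $2^{-\Delta\Delta C_t}$ formula recovers them bit-cleanly; technical
  noise can be added when robustness rather than correctness is being
  tested.

What the generator does *not* emulate: read-level effects (GC,
fragment length, mapping ambiguity), correlated genes, outlier
replicates, and composition bias. Passing calibration here shows the
procedure is correct under its own assumptions, not that real
libraries satisfy them.

# Normalization

`equalize_depth()` downsamples every sample, without replacement, to
the minimum column total, drawing each column from the multivariate
hypergeometric distribution with the gene counts as category sizes —
the exact distribution of gene labels when reads are subsampled
uniformly. Column totals are therefore *exactly* equal integers, each
count is bounded by its original, and the expectation of each
downsampled count is the original times the depth ratio. Binomial
thinning is offered as an option (`method = "binomial"`) but preserves
totals only in expectation. Deeper normalization of highly expressed,
highly variable elements is deliberately not attempted: no
quantitative rule is defensible from first principles here.

# Calibration results the tests compute

Two headline properties are verified by the test suite (and the first
recomputed by `scripts/acceptance.R`):

* **FDR calibration** — over 200 seeded simulations at the default
  conditions (`n_genes = 10000`, `pi1 = 0.1`, effect 2.0, dispersion
  0.1), the mean realized false-discovery proportion of the level-0.5
  putative list is within 5 percentage points of 50%.
* **Propagation power and false-alarm control** — with one set planted
  at $\rho = 10$ the verdict flags it in the majority of 100 seeds
  (in practice, nearly all); with $\rho = 1$ a flag at $10^{-4}$ is
  rare. The planted set's enrichment p degrades monotonically (in
  medians) as the nominal level rises through 0.5, 0.7, 0.9 — the
  dilution effect. The comparison starts at 0.5 because below it the
  two-permutation scheme yields lists of a handful of genes whose
  enrichment p is dominated by list size, not dilution; with only two
  permutations the estimated FDR rarely dips under ~0.25 except at the
  extreme top of the spectrum.

Note the permutation null is computed from data that *contain* the
planted effects: the mixed relabelings inherit inflated within-group
variance from DE genes, which makes the spectrum ratio mildly
conservative. At the default conditions this bias is negligible
(realized FDP ≈ 0.50); at much larger `pi1` or effect sizes the
realized FDP falls below nominal.

# Guide and repair-template arithmetic

All coordinates are 0-based half-open. `scan_pams()` reports every NGG
on both strands with room for a full protospacer (default 20 nt;
configurable — the constructs this package was built around used 23-nt
protospacers), with the blunt SpCas9 cut placed 3 bp 5′ of the PAM.
`select_flanking_pairs()` applies the excision constraint for a
three-SNP haplotype block — first cut strictly downstream of SNP 1,
second cut strictly upstream of SNP 3, first before second — exactly
as stated, ranking pairs that cover the middle SNP first, longer
excisions first. `build_insert_oligos()` emits the
`CACC`/`AAAC`-adapter oligo pair matching BbsI-digested expression
vectors; the optional `G` prepend for U6 transcription is off by
default since the reference constructs show none. One published
forward oligo carries a 5-nt `CAACC` prefix that is not reconcilable
with the 4-nt overhang scheme its own reverse oligo follows; the
builder emits `CACC`, and tests compare that insert via its
adapter-stripped guide and its reverse oligo, which round-trip
exactly. `build_hdr_template()` substitutes requested alleles (each
validated against ref/alt) into the amplicon, leaving length and all
other positions unchanged. Off-target specificity scoring is out of
scope — candidates carry no genome-wide scores.

# Descriptive summaries

`cluster_samples()` is Euclidean-distance agglomerative clustering of
samples on `log2(count + 1)`, restricted to a gene list (typically the
union of putative sets); linkage defaults to average since the method
description pins only the metric, and `stats::hclust`'s deterministic
merge order fixes ties. Trees serialize to Newick via `ape`.
`venn_counts()` and `ddct_fold_change()` are the exact set partition
and the standard $2^{-\Delta\Delta C_t}$ quantification; the
calibrator defaults to the table's designated sample and its own fold
is exactly 1.

# Known limitations

* Two permutations give a coarse, high-variance FDR curve; the
  monotone envelope makes it usable but cannot add resolution. Levels
  below ~0.25 are effectively unreachable in the 2-vs-2 design.
* The screen's verdict is one-sided by construction: "not clean" is
  evidence of perturbation, while "clean" bounds only what the
  propagation argument can see — pathway-coherent effects of the size
  the list can carry.
* The hypergeometric background is the post-filter gene universe;
  knowledge-base tests with curated backgrounds will differ.
* `perm_fdr()` handles one two-group contrast; multi-condition designs
  are run as separate contrasts against the shared control.
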