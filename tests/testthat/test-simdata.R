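test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(pi1 = 1.2), "pi1")
  expect_error(sim_config(n_genes = 100, pi1 = 0.001), "pi1")
  expect_error(sim_config(set_size = 200, n_genes = 100), "set_size")
  expect_error(sim_config(enrichment_rho = 0.5), "enrichment_rho")
  expect_error(sim_config(rrna_fraction = 1), "rrna_fraction")
})

test_that("simulate_counts is seed-deterministic and respects pi1 = 0", {
  cfg <- sim_config(n_genes = 300, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  z <- simulate_counts(sim_config(n_genes = 300, pi1 = 0, seed = 7))
  expect_length(z$truth$de_genes, 0)
  expect_true(all(z$truth$signed_log2fc == 0))
})

test_that("simulated matrix has the promised shape and truth bookkeeping", {
  cfg <- sim_config(n_genes = 400, n_per_group = 3, pi1 = 0.1, seed = 2)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  expect_s3_class(m, "count_matrix")
  expect_equal(dim(m), c(400L, 6L))
  expect_setequal(unique(unname(m$groups)), c("treated", "control"))
  expect_true(all(m$counts >= 0))
  expect_identical(storage.mode(m$counts), "integer")
  expect_true(all(sim$truth$de_genes %in% rownames(m$counts)))
  expect_equal(sim$truth$n_de, length(sim$truth$de_genes))
  # planted effects have the stated magnitude, random sign
  lfc <- sim$truth$signed_log2fc[sim$truth$de_genes]
  expect_true(all(abs(lfc) == cfg$effect_log2fc))
})

test_that("counts follow the negative-binomial mean-variance law", {
  cfg <- sim_config(n_genes = 10000, dispersion = 0.1, pi1 = 0.05,
                    n_per_group = 10, library_size_cv = 0, seed = 11)
  sim <- simulate_counts(cfg)
  nonde <- setdiff(rownames(sim$matrix$counts), sim$truth$de_genes)
  m <- rowMeans(sim$matrix$counts[nonde, ])
  v <- apply(sim$matrix$counts[nonde, ], 1, var)
  keep <- m > 20
  # method-of-moments fit of Var = mean + phi * mean^2; oracle = the
  # generating value phi = 0.1, tolerance 20%
  fit <- lm(I(v - m) ~ 0 + I(m^2), weights = 1 / (m + 1)^4, subset = keep)
  phi_hat <- unname(coef(fit))
  expect_gt(phi_hat, 0.1 * 0.8)
  expect_lt(phi_hat, 0.1 * 1.2)
})

test_that("non-DE genes have equal group means: t-test rejects at ~5%", {
  # property: two-sided alpha = 0.05 rejection rate across genes/seeds
  rej <- unlist(lapply(1:20, function(s) {
    sim <- simulate_counts(sim_config(n_genes = 300, pi1 = 0,
                                      n_per_group = 5,
                                      library_size_cv = 0, seed = s))
    g <- sim$matrix$groups
    apply(sim$matrix$counts, 1, function(x) {
      a <- x[g == "treated"]; b <- x[g == "control"]
      if (var(a) + var(b) == 0) return(1)
      t.test(a, b)$p.value
    })
  }))
  rate <- mean(rej < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("gene sets: no planted enrichment means DE fraction ~ pi1", {
  # 200 seeds, Monte-Carlo check of the membership law at rho = 1
  fr <- vapply(1:200, function(s) {
    cfg <- sim_config(n_genes = 1000, pi1 = 0.1, n_sets = 2, set_size = 100,
                      enrichment_rho = 1, seed = s)
    sim <- simulate_counts(cfg)
    gs <- simulate_gene_sets(cfg, sim$truth)
    mean(vapply(gs$sets, function(x)
      mean(x %in% sim$truth$de_genes), numeric(1)))
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.1), 4 * se + 1e-9)
  expect_length(attr(simulate_gene_sets(
    sim_config(n_genes = 1000, pi1 = 0.1, enrichment_rho = 1, seed = 1),
    simulate_counts(sim_config(n_genes = 1000, pi1 = 0.1, seed = 1))$truth),
    "enriched_sets"), 0)
})

test_that("rho = 5 sets carry more DE genes than unenriched sets", {
  res <- vapply(1:200, function(s) {
    cfg <- sim_config(n_genes = 1000, pi1 = 0.05, n_sets = 4, set_size = 100,
                      enrichment_rho = 5, n_enriched = 2, seed = s)
    sim <- simulate_counts(cfg)
    gs <- simulate_gene_sets(cfg, sim$truth)
    en <- attr(gs, "enriched_sets")
    de <- sim$truth$de_genes
    c(mean(vapply(gs$sets[en], function(x) sum(x %in% de), numeric(1))),
      mean(vapply(gs$sets[setdiff(names(gs$sets), en)],
                  function(x) sum(x %in% de), numeric(1))))
  }, numeric(2))
  expect_gt(mean(res[1, ]), mean(res[2, ]))
  # planted Fisher p stochastically smaller on enriched sets
  cfg <- sim_config(n_genes = 2000, pi1 = 0.05, n_sets = 4, set_size = 100,
                    enrichment_rho = 8, n_enriched = 2, seed = 5)
  sim <- simulate_counts(cfg)
  gs <- simulate_gene_sets(cfg, sim$truth)
  res <- enrich_collection(sim$truth$de_genes, gs)
  en <- attr(gs, "enriched_sets")
  expect_lt(max(res$p_value[res$set %in% en]),
            min(res$p_value[!res$set %in% en]))
})

test_that("n_sets = 0 yields an empty collection", {
  cfg <- sim_config(n_genes = 200, n_sets = 0, seed = 1)
  sim <- simulate_counts(cfg)
  gs <- simulate_gene_sets(cfg, sim$truth)
  expect_length(gs$sets, 0)
  expect_setequal(gs$universe, rownames(sim$matrix$counts))
})

test_that("Ct table generator plants recoverable fold changes", {
  expect_error(simulate_ct_table(0), "n_samples")
  a <- simulate_ct_table(6, seed = 4)
  b <- simulate_ct_table(6, seed = 4)
  expect_identical(a, b)
  # all folds 1 when target tracks the calibrator offset everywhere
  expect_equal(unname(ddct_fold_change(a)), rep(1, 6))
  # planted fold 4 inverts through 2^-ddCt within 2^(+/-0.1)
  ct <- simulate_ct_table(5, seed = 2, fold = c(1, 4, 1, 1, 1))
  f <- ddct_fold_change(ct)
  expect_gt(f[["sample_2"]], 4 * 2^-0.1)
  expect_lt(f[["sample_2"]], 4 * 2^0.1)
  expect_true(all(a$ct_target >= 15 & a$ct_target <= 35))
})
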