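test_that("pooled-variance t statistics match hand evaluation", {
  m <- matrix(c(10, 12, 20, 22), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  t <- row_t_stats(m, groups = c("a", "a", "b", "b"), transform = "raw")
  expect_equal(abs(unname(t)), 10 / sqrt(2), tolerance = 1e-12)

  # identical values in both groups, and a fully constant gene: t = 0
  m2 <- rbind(g1 = c(5, 7, 5, 7), g2 = c(3, 3, 3, 3))
  colnames(m2) <- paste0("s", 1:4)
  t2 <- row_t_stats(m2, groups = c("a", "a", "b", "b"), transform = "raw")
  expect_identical(unname(t2), c(0, 0))
  expect_false(anyNA(t2))

  # a group with fewer than 2 samples is refused
  expect_error(row_t_stats(m2[, 1:3], groups = c("a", "a", "b")),
               "at least 2")
  # epsilon stabilizer shrinks the statistic
  m3 <- matrix(c(10, 12, 20, 22), 1, dimnames = list("g", paste0("s", 1:4)))
  t_eps <- row_t_stats(m3, c("a", "a", "b", "b"), transform = "raw",
                       epsilon = 1)
  expect_lt(abs(t_eps), abs(t))
})

test_that("balanced permutations enumerate the mixed partitions", {
  sch <- balanced_permutations(c("T1", "T2", "C1", "C2"),
                               c("t", "t", "c", "c"))
  expect_equal(sch$n, 2L)
  groups_of <- function(lab) {
    sort(vapply(split(names(lab), lab),
                function(x) paste(sort(x), collapse = "+"), character(1)))
  }
  parts <- lapply(sch$partitions, groups_of)
  expect_true(any(vapply(parts, function(p)
    setequal(p, c("C1+T1", "C2+T2")), logical(1))))
  expect_true(any(vapply(parts, function(p)
    setequal(p, c("C2+T1", "C1+T2")), logical(1))))
  # every relabeling preserves group sizes; observed labeling excluded
  for (p in sch$partitions) {
    expect_equal(unname(table(p)), unname(table(c("t", "t", "c", "c"))))
    expect_false(identical(unname(p), c("t", "t", "c", "c")))
  }
})

test_that("scheme size matches brute-force enumeration for 3-vs-3", {
  ids <- paste0("s", 1:6)
  g <- rep(c("t", "c"), each = 3)
  sch <- balanced_permutations(ids, g)
  # oracle: enumerate all label vectors, dedupe swaps, drop observed
  all_lab <- combn(6, 3, simplify = FALSE)
  canon <- unique(lapply(all_lab, function(s) {
    if (1 %in% s) s else setdiff(1:6, s)
  }))
  canon <- Filter(function(s) !identical(s, 1:3), canon)
  expect_equal(sch$n, length(canon))
  expect_equal(sch$n, choose(6, 3) / 2 - 1)   # 9

  # 1-vs-1 admits no non-observed balanced relabeling
  expect_error(balanced_permutations(c("a", "b"), c("t", "c")),
               "no balanced relabeling")
})

test_that("FDR curve equals exhaustive enumeration on a tiny instance", {
  set.seed(42)
  m <- matrix(c(50L, 60L, 10L, 12L,
                5L,  6L,  50L, 40L,
                20L, 22L, 21L, 19L,
                100L, 90L, 95L, 105L,
                3L,  30L, 7L,  25L), nrow = 5, byrow = TRUE)
  cm <- cm_2v2(m)
  fit <- perm_fdr(cm, level = 0.5)
  oracle <- brute_force_fdr(m)
  expect_equal(unname(abs(fit$t_obs)), abs(oracle$t_obs), tolerance = 1e-12)
  expect_equal(fit$grid, oracle$grid, tolerance = 1e-12)
  expect_equal(fit$fdr_raw, oracle$raw, tolerance = 1e-12)
  expect_equal(fit$fdr_curve, oracle$curve, tolerance = 1e-12)

  # putative set = genes at or above the least stringent qualifying cutoff
  ok <- oracle$curve <= 0.5
  if (any(ok)) {
    tstar <- min(oracle$grid[ok])
    expect_setequal(fit$putative_set,
                    rownames(cm$counts)[abs(oracle$t_obs) >= tstar])
  } else {
    expect_length(fit$putative_set, 0)
  }
})

test_that("FDR curve is a clipped, monotone spectrum ratio", {
  sim <- simulate_counts(sim_config(n_genes = 800, pi1 = 0.1, seed = 13))
  fit <- perm_fdr(sim$matrix)
  expect_true(all(fit$fdr_curve >= 0 & fit$fdr_curve <= 1))
  # grid descending; curve non-increasing in the cutoff
  expect_true(all(diff(fit$grid) < 0))
  expect_true(all(diff(fit$fdr_curve) >= 0))   # along descending grid
  expect_true(all(fit$fdr_curve <= fit$fdr_raw + 1e-12))
  # definition at a cutoff: ratio of permutation-mean to observed counts
  i <- which.max(fit$grid <= median(abs(fit$t_obs)))
  expect_equal(fit$fdr_raw[i],
               min(1, fit$perm_exceedance_mean[i] / fit$obs_exceedance[i]))
})

test_that("pure-null spectra give FDR ~ 1 and usually no putative set", {
  # permuted spectra identical to observed at every cutoff => ratio 1:
  # a matrix symmetric under relabeling
  m <- matrix(c(10L, 20L, 10L, 20L,
                7L, 3L, 7L, 3L,
                1L, 9L, 1L, 9L), nrow = 3, byrow = TRUE)
  fit <- perm_fdr(cm_2v2(m))
  # observed groups {10,20} vs {10,20}: t = 0 for all genes; every
  # permuted statistic is >= 0 in magnitude, so the ratio is 1 everywhere
  expect_true(all(fit$fdr_curve == 1))
  expect_length(extract_putative_set(fit, 0.5), 0)

  # with pi1 = 0, seeds rarely produce any gene at level 0.5
  hits <- vapply(1:30, function(s) {
    sim <- simulate_counts(sim_config(n_genes = 500, pi1 = 0, seed = s))
    length(perm_fdr(sim$matrix)$putative_set) > 0
  }, logical(1))
  expect_lt(mean(hits), 0.5)
})

test_that("level extraction validates input and honors the definition", {
  sim <- simulate_counts(sim_config(n_genes = 600, pi1 = 0.15, seed = 21))
  fit <- perm_fdr(sim$matrix)
  expect_error(extract_putative_set(fit, 0), "level")
  expect_error(extract_putative_set(fit, 1.5), "level")
  ps <- extract_putative_set(fit, 0.5)
  ok <- fit$fdr_curve <= 0.5
  if (any(ok)) {
    tstar <- min(fit$grid[ok])
    expect_setequal(ps, names(fit$t_obs)[abs(fit$t_obs) >= tstar])
  }
  # a stricter level never yields a larger list
  expect_lte(length(extract_putative_set(fit, 0.25)), length(ps))
})

test_that("screen is invariant under permuting the sample columns", {
  sim <- simulate_counts(sim_config(n_genes = 400, pi1 = 0.1, seed = 17))
  cm <- sim$matrix
  fit1 <- perm_fdr(cm)
  perm <- c(3, 1, 4, 2)
  cm2 <- count_matrix(cm$counts[, perm], groups = cm$groups[perm])
  fit2 <- perm_fdr(cm2)
  expect_equal(abs(fit1$t_obs), abs(fit2$t_obs))
  expect_equal(fit1$fdr_curve, fit2$fdr_curve)
  expect_setequal(fit1$putative_set, fit2$putative_set)
})

test_that("model-object methods behave", {
  sim <- simulate_counts(sim_config(n_genes = 300, pi1 = 0.1, seed = 5))
  fit <- perm_fdr(sim$matrix)
  expect_s3_class(fit, "perm_fdr")
  expect_output(print(fit), "putative set")
  s <- summary(fit)
  expect_s3_class(s, "summary.perm_fdr")
  expect_output(print(s), "Putative-set size")
  expect_identical(coef(fit), fit$t_obs)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
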