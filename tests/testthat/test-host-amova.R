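test_that("homozygous single-allele data degenerate to zero components", {
  g <- toy_genotypes()
  g$individuals$allele_a <- "a1"
  g$individuals$allele_b <- "a1"
  res <- hier_amova(g$individuals, allele_dist = g$allele_dist, n_perm = 0)
  expect_true(res$degenerate)
  expect_equal(res$table$sumsq, rep(0, 4))
  expect_equal(res$table$phi, rep(0, 4))
})

test_that("group-fixed homozygotes put all variation among groups", {
  g <- toy_genotypes(n_ind = 8)
  g$individuals$allele_a <- ifelse(g$individuals$group == "g1", "a1", "a2")
  g$individuals$allele_b <- g$individuals$allele_a
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a1", "a2"),
                                                c("a1", "a2")))
  res <- hier_amova(g$individuals, allele_dist = d, n_perm = 0)
  tab <- tidy(res)
  expect_equal(tab$pct_variation[tab$level == "among_groups"], 100,
               tolerance = 1e-10)
  expect_equal(tab$phi[tab$level == "among_groups"], 1, tolerance = 1e-10)
})

test_that("sums of squares match the explicit allele-pair oracle", {
  for (seed in c(2, 9, 14)) {
    g <- toy_genotypes(seed = seed)
    res <- hier_amova(g$individuals, allele_dist = g$allele_dist, n_perm = 0)
    want <- oracle_hier_amova(g$individuals, g$allele_dist)
    tab <- tidy(res)
    expect_equal(tab$sumsq,
                 c(want$ss_among_groups, want$ss_among_samples,
                   want$ss_among_individuals, want$ss_within_individuals),
                 tolerance = 1e-10)
    expect_equal(sum(tab$pct_variation), 100, tolerance = 1e-6)
    # df arithmetic for the nesting
    expect_equal(tab$df, c(2 - 1, 4 - 2, 12 - 4, 12))
  }
})

test_that("allele sequences can stand in for a distance matrix", {
  g <- toy_genotypes(n_alleles = 3)
  seqs <- c(a1 = "AAAAAA", a2 = "AATAAA", a3 = "TTTAAA")
  res <- hier_amova(g$individuals, allele_seqs = seqs, n_perm = 0)
  d <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3,
              dimnames = list(names(seqs), names(seqs)))
  res2 <- hier_amova(g$individuals, allele_dist = d, n_perm = 0)
  expect_equal(tidy(res)$sumsq, tidy(res2)$sumsq, tolerance = 1e-12)
})

test_that("genotype errors are caught", {
  g <- toy_genotypes()
  bad <- g$individuals
  bad$allele_b[1] <- NA
  expect_error(hier_amova(bad, allele_dist = g$allele_dist), "missing allele")
  one_group <- g$individuals
  one_group$group <- "g1"
  expect_error(hier_amova(one_group, allele_dist = g$allele_dist),
               ">= 2 groups")
})

test_that("permutation p-values are seeded and bounded", {
  g <- toy_genotypes(seed = 6)
  r1 <- hier_amova(g$individuals, allele_dist = g$allele_dist,
                   n_perm = 99, seed = 3)
  r2 <- hier_amova(g$individuals, allele_dist = g$allele_dist,
                   n_perm = 99, seed = 3)
  expect_identical(tidy(r1)$p_perm, tidy(r2)$p_perm)
  expect_true(all(tidy(r1)$p_perm >= 1 / 100 & tidy(r1)$p_perm <= 1))
})

test_that("exact enumeration matches closed forms and fisher.test", {
  # identical columns: observed table is the most probable one
  res <- exact_test(matrix(c(5, 5, 5, 5), 2), enumerate_limit = 20)
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "enumeration")
  # diagonal 2x2: hypergeometric two-tail
  res2 <- exact_test(matrix(c(5, 0, 0, 5), 2), enumerate_limit = 10)
  expect_equal(res2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # independent oracle on assorted small tables
  tabs <- list(matrix(c(3, 1, 1, 4), 2), matrix(c(2, 0, 1, 3, 2, 1), 2),
               matrix(c(1, 1, 2, 2, 1, 1, 0, 2, 1), 3))
  for (tb in tabs) {
    mine <- exact_test(tb, enumerate_limit = 12)$p_value
    ft <- stats::fisher.test(tb)$p.value
    expect_equal(mine, ft, tolerance = 1e-8)
  }
})

test_that("Markov-chain estimate tracks the enumeration", {
  tb <- matrix(c(4, 1, 2, 5), 2)
  exact <- exact_test(tb, enumerate_limit = 12)$p_value
  chain <- exact_test(tb, enumerate_limit = 0, chain_steps = 50000,
                      seed = 2)$p_value
  expect_equal(chain, exact, tolerance = 0.03)
  expect_error(exact_test(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})
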