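test_that("PSI reproduces desk-checked colony values", {
  # all-clade-D colony
  expect_equal(round2up(psi(c(D1a = 7, D1 = 1, D1a.1 = 1),
                            c(D1a = 5, D1a.1 = 3, D1 = 2))), 0.72)
  # pseudogene-dependent colony: egg reduces to a single shared variant
  expect_equal(round2up(psi(c(C31 = 5, C31.2 = 2, C21 = 2, C17 = 1),
                            c(C31 = 1))), 0.50)
  expect_equal(psi(c(C31 = 3), c(C31 = 7)), 1)
  expect_equal(psi(c(C31 = 3), c(D1 = 7)), 0)
  expect_error(psi(c(C31 = 0), c(C31 = 1)), "empty")
})

test_that("PSI is symmetric and scale-invariant", {
  set.seed(7)
  for (rep in 1:25) {
    labs <- paste0("v", 1:6)
    a <- setNames(rpois(6, 3), labs)
    b <- setNames(rpois(6, 3), labs)
    a <- a[a > 0]
    b <- b[b > 0]
    if (length(a) == 0 || length(b) == 0) next
    expect_equal(psi(a, b), psi(b, a))
    expect_equal(psi(a * 7, b), psi(a, b))
    expect_gte(psi(a, b), 0)
    expect_lte(psi(a, b), 1 + 1e-12)
  }
})

test_that("two-group Phi equals the explicit double-loop oracle", {
  set.seed(101)
  for (rep in 1:50) {
    toy <- random_toy_libraries()
    got <- pairwise_phi(toy$d, toy$group)
    want <- oracle_pair_amova(toy$d, toy$group)
    expect_equal(got$phi, want$phi, tolerance = 1e-12)
    expect_equal(got$sigma2_among, want$sigma2_among, tolerance = 1e-12)
    expect_equal(got$sigma2_within, want$sigma2_within, tolerance = 1e-12)
  }
})

test_that("alternate fixation gives Phi exactly 1", {
  labs <- rep(c("h1", "h3"), each = 4)
  d <- matrix(10, 8, 8, dimnames = list(labs, labs))
  d[1:4, 1:4] <- 0
  d[5:8, 5:8] <- 0
  res <- pairwise_phi(d, rep(c("a", "b"), each = 4))
  expect_identical(res$phi, 1)
})

test_that("identical groups give the oracle's (non-positive) Phi and p near 1", {
  labs <- rep(c("h1", "h2"), 8)
  dv <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("h1", "h2"), c("h1", "h2")))
  d <- dv[labs, labs]
  group <- rep(c("a", "b"), each = 8)
  res <- permutation_test(d, group, n_perm = 199, seed = 8)
  expect_equal(res$phi, oracle_pair_amova(d, group)$phi, tolerance = 1e-12)
  expect_lte(res$phi, 0)
  expect_gt(res$p_value, 0.5)
})

test_that("mixed two-library case matches the frozen oracle value", {
  # A = {h1 x3, h2 x1}, B = {h3 x4}; d(h1,h2)=1, d(h1,h3)=d(h2,h3)=10
  labs <- c(rep("h1", 3), "h2", rep("h3", 4))
  dv <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("h1", "h2", "h3"), c("h1", "h2", "h3")))
  d <- dv[labs, labs]
  group <- rep(c("A", "B"), c(4, 4))
  want <- oracle_pair_amova(d, group)
  got <- pairwise_phi(d, group)
  expect_equal(got$phi, want$phi, tolerance = 1e-12)
  expect_gt(got$phi, 0.9)  # near-fixation with one off variant
})

test_that("permutation p is seeded, add-one bounded, relabel-invariant", {
  toy <- withr::with_seed(33, random_toy_libraries())
  r1 <- permutation_test(toy$d, toy$group, n_perm = 99, seed = 5)
  r2 <- permutation_test(toy$d, toy$group, n_perm = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 1)
  # relabel variants (permute matrix rows consistently with groups intact)
  n <- nrow(toy$d)
  relab <- toy$d
  dimnames(relab) <- list(paste0("z", seq_len(n)), paste0("z", seq_len(n)))
  r3 <- permutation_test(relab, toy$group, n_perm = 99, seed = 5)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("separated groups are detected by the permutation test", {
  labs <- rep(c("h1", "h3"), each = 8)
  d <- matrix(10, 16, 16, dimnames = list(labs, labs))
  d[1:8, 1:8] <- 0
  d[9:16, 9:16] <- 0
  res <- permutation_test(d, rep(c("a", "b"), each = 8), n_perm = 999,
                          seed = 3)
  expect_lt(res$p_value, 0.05)
})

test_that("tidy and glance expose the pair-AMOVA pieces", {
  toy <- withr::with_seed(12, random_toy_libraries())
  res <- permutation_test(toy$d, toy$group, n_perm = 49, seed = 2)
  td <- tidy(res)
  expect_equal(td$term, c("among_groups", "within_groups"))
  expect_equal(sum(td$sumsq), res$ss_total, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(gl$n_permutations, 49L)
})
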