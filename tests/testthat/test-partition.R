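sim_small_clone_dist <- function(seed, n_colonies = 3, sites = c("S1", "S2"),
                                 site_d_weight = 0.8, aligned_length = 80) {
  cfg <- sim_config(aligned_length = aligned_length, sites = sites,
                    n_colonies_per_site = n_colonies, morph_site = NULL,
                    site_d_weight = site_d_weight)
  sim <- simulate_bundle(cfg, seed = seed)
  libs <- sim$bundle$libraries
  vd <- sqrt_transform(variant_distance_matrix(sim$bundle$variants))
  clone_distance_matrix(libs, vd)
}

test_that("Gower centering reproduces the total sum of squares", {
  expect_equal(gower_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  g2 <- gower_center(matrix(c(0, 2, 2, 0), 2))
  expect_equal(sum(diag(g2)), 2)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample.int(9, sum(upper.tri(d)), replace = TRUE)
    d <- d + t(d)
    expect_equal(sum(diag(gower_center(d))), oracle_trace_ss(d),
                 tolerance = 1e-10)
  }
})

test_that("one-way partition agrees with the two-group AMOVA and adonis2", {
  toy <- withr::with_seed(55, random_toy_libraries(max_clones = 8))
  clones <- tibble::tibble(
    sample_id = toy$group, variant = toy$labels, count = 1L,
    colony_id = toy$group, site = "X", year = 2007L,
    life_stage = toy$group, morphology = "unknown")
  cd <- list(d = new_sym_dist_for_test(toy$d), clones = clones)
  class(cd) <- "sym_clone_dist"
  des <- sym_design("life_stage", n_permutations = 0)
  fit <- suppressWarnings(fit_partition(cd, des))
  tab <- tidy(fit)
  pair <- pairwise_phi(toy$d, toy$group)
  # same SS decomposition
  expect_equal(tab$sumsq[tab$term == "life_stage"], pair$ss_among,
               tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "Residual"], pair$ss_within,
               tolerance = 1e-10)
  # pseudo-F equals the AMOVA mean-square ratio
  f_amova <- (pair$ss_among / 1) / (pair$ss_within / (nrow(toy$d) - 2))
  expect_equal(tab$pseudo_f[tab$term == "life_stage"], f_amova,
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(stats::as.dist(toy$d) ~ grp,
                       data = data.frame(grp = toy$group), permutations = 0)
  expect_equal(tab$sumsq[tab$term == "life_stage"], ad$SumOfSqs[1],
               tolerance = 1e-8)
})

test_that("sequential SS are additive for the built-in designs", {
  cd <- sim_small_clone_dist(seed = 17)
  des <- builtin_designs(n_permutations = 0)$four_factor
  fit <- fit_partition(cd, des)
  tab <- tidy(fit)
  ss_total <- tab$sumsq[tab$term == "Total"]
  expect_equal(sum(tab$sumsq[!tab$term %in% c("Total")]), ss_total,
               tolerance = 1e-8)
  expect_equal(sum(tab$df[!tab$term %in% c("Total")]),
               tab$df[tab$term == "Total"])
  # three-factor design on a morphology site
  cfg <- sim_config(aligned_length = 80, n_colonies_per_site = 2,
                    n_colonies_per_morph = 3)
  sim <- simulate_bundle(cfg, seed = 23)
  morph <- dplyr::filter(sim$bundle$libraries, morphology != "unknown")
  vd <- sqrt_transform(variant_distance_matrix(sim$bundle$variants))
  cd3 <- clone_distance_matrix(morph, vd)
  fit3 <- fit_partition(cd3, builtin_designs(n_permutations = 0)$three_factor)
  t3 <- tidy(fit3)
  expect_equal(sum(t3$sumsq[!t3$term %in% "Total"]),
               t3$sumsq[t3$term == "Total"], tolerance = 1e-8)
})

test_that("built-in designs carry the published term lists", {
  des <- builtin_designs()
  expect_length(des$four_factor$terms, 11)
  expect_length(des$three_factor$terms, 5)
  expect_equal(des$four_factor$terms[1:4],
               c("site", "year", "life_stage", "colony_id %in% site"))
  expect_equal(des$four_factor$n_permutations, 10000L)
})

test_that("rank-deficient terms error with the term named", {
  cd <- sim_small_clone_dist(seed = 31)
  des <- sym_design(c("site", "site"), n_permutations = 0)
  expect_error(fit_partition(cd, des), "rank-deficient.*site")
})

test_that("a strong site effect is detected; a null term is not", {
  cd <- sim_small_clone_dist(seed = 77, site_d_weight = 0.9)
  des <- sym_design(c("site", "life_stage"), n_permutations = 199, seed = 1)
  tab <- tidy(fit_partition(cd, des))
  expect_lt(tab$p_perm[tab$term == "site"], 0.05)
  expect_gt(tab$p_perm[tab$term == "life_stage"], 0.05)
})

test_that("library-level permutation keeps clones of a sample together", {
  cd <- sim_small_clone_dist(seed = 13)
  des <- sym_design("site", n_permutations = 99, permute = "library",
                    seed = 4)
  fit <- fit_partition(cd, des)
  expect_true(all(tidy(fit)$p_perm >= 0.01, na.rm = TRUE))
})
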