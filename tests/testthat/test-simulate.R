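test_that("the same seed reproduces a bundle exactly", {
  cfg <- sim_config(aligned_length = 80, n_colonies_per_site = 2)
  s1 <- simulate_bundle(cfg, seed = 42)
  s2 <- simulate_bundle(cfg, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_bundle(cfg, seed = 43)
  expect_false(identical(s1$bundle$libraries, s3$bundle$libraries))
})

test_that("recorded satellite edits equal recomputed distances", {
  cfg <- sim_config(aligned_length = 150, satellites_per_dominant = 4)
  mv <- make_variants(cfg, seed = 8)
  d <- unclass(variant_distance_matrix(mv$variants))
  sats <- dplyr::filter(mv$truth, !is.na(parent))
  expect_gt(nrow(sats), 0)
  for (i in seq_len(nrow(sats))) {
    expect_equal(d[sats$label[i], sats$parent[i]], sats$n_edits[i])
  }
  expect_true(all(sats$n_edits %in% 1:3))
})

test_that("a minimal config yields two variants at the set divergence", {
  cfg <- sim_config(aligned_length = 100, interclade_divergence = 0.25,
                    dominants_per_clade = c(C = 1L, D = 1L),
                    satellites_per_dominant = 0L)
  mv <- make_variants(cfg, seed = 2)
  expect_equal(nrow(mv$variants), 2)
  d <- unclass(variant_distance_matrix(mv$variants))
  expect_equal(d["C1", "D1"], 25)
})

test_that("injected pseudogene labels are excluded by screening", {
  cfg <- sim_config(aligned_length = 80,
                    pseudogene_labels = "C1.1", n_colonies_per_site = 3)
  sim <- simulate_bundle(cfg, seed = 6)
  expect_true(sim$bundle$variants$pseudogene[
    sim$bundle$variants$label == "C1.1"])
  sc <- screen_variants(sim$bundle$libraries, sim$bundle$variants)
  if ("C1.1" %in% sc$label) {
    expect_equal(sc$status[sc$label == "C1.1"], "excluded")
    expect_equal(sc$reason[sc$label == "C1.1"], "pseudogene")
  }
})

test_that("library sizes stay inside the configured range", {
  cfg <- sim_config(aligned_length = 80, n_colonies_per_site = 4)
  sim <- simulate_bundle(cfg, seed = 10)
  tot <- dplyr::summarise(
    dplyr::group_by(sim$bundle$libraries, sample_id),
    n = sum(count), .groups = "drop")
  expect_true(all(tot$n >= 7 & tot$n <= 13))
  expect_length(validate_bundle(sim$bundle), 0)
  expect_error(simulate_bundle(sim_config(n_colonies_per_site = 0)),
               ">= 1")
})

test_that("faithful transmission yields high parent-egg similarity", {
  # large-library, low-noise regime: sampling error vanishes and the egg
  # assemblage converges on the parental composition
  cfg <- sim_config(aligned_length = 60, n_colonies_per_site = 2,
                    morph_site = NULL, egg_model = "faithful",
                    library_size_range = c(300L, 300L),
                    overdispersion = 500)
  med <- vapply(1:40, function(s) {
    sim <- simulate_bundle(cfg, seed = s)
    pt <- pair_stats(sim$bundle$libraries, sim$bundle$variants)
    stats::median(pt$psi)
  }, numeric(1))
  expect_gt(stats::median(med), 0.8)
})

test_that("shifted transmission raises stage differentiation", {
  base <- sim_config(aligned_length = 60, n_colonies_per_site = 2,
                     morph_site = NULL, site_d_weight = 0.95,
                     years = 2007L)
  shift <- base
  shift$egg_model <- "shifted"
  wins <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    phi_for <- function(cfg) {
      sim <- simulate_bundle(cfg, seed = s)
      libs <- dplyr::filter(sim$bundle$libraries, site == cfg$sites[1])
      vd <- variant_distance_matrix(sim$bundle$variants)
      mean(vapply(unique(libs$colony_id), function(co) {
        sub <- dplyr::filter(libs, colony_id == co)
        cd <- clone_distance_matrix(sub, vd)
        pairwise_phi(cd$d, cd$clones$life_stage)$phi
      }, numeric(1)))
    }
    if (phi_for(shift) > phi_for(base)) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.9)
})

test_that("truth-record weights are recoverable from generated counts", {
  cfg <- sim_config(aligned_length = 60, n_colonies_per_site = 1,
                    morph_site = NULL, years = 2007L,
                    library_size_range = c(200L, 200L),
                    overdispersion = 1e6)
  sim <- simulate_bundle(cfg, seed = 77)
  first <- dplyr::filter(sim$bundle$libraries, life_stage == "adult")$sample_id[1]
  lib <- dplyr::filter(sim$bundle$libraries, sample_id == first)
  w <- dplyr::filter(sim$truth$weights, sample_id == first)
  est <- lib$count / sum(lib$count)
  names(est) <- lib$variant
  for (v in names(est)) {
    p <- w$weight[w$variant == v]
    # binomial sampling error bound at n = 200
    expect_lt(abs(est[[v]] - p), 4 * sqrt(p * (1 - p) / 200) + 0.01)
  }
})
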