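#' Configuration for the synthetic clone-library generator
#'
#' The generator emulates the structure of ITS2 clone-library surveys of
#' parent corals and their eggs: two deeply divergent symbiont clades (C
#' and D), a few dominant haplotypes per clade with low-abundance
#' satellites 1-3 substitutions away, small clone libraries of 7-13
#' sequences per sample, site-dependent clade composition, and an egg
#' assemblage either mirroring the parent (`faithful`) or shifted towards
#' clade C for clade-D-dominated parents (`shifted`).
#'
#' @param aligned_length Aligned sequence length (default 320).
#' @param dominants_per_clade Named integer vector, dominant haplotypes per
#'   clade (default `c(C = 3, D = 2)`).
#' @param satellites_per_dominant Satellites generated around each dominant
#'   (default 3).
#' @param variant_edit_range Satellite distance to its dominant, inclusive
#'   range (default `c(1, 3)`).
#' @param interclade_divergence Proportion of positions differing between
#'   the clade C and clade D ancestors (default 0.25; a stand-in, not an
#'   empirical figure).
#' @param sites Character vector of main study sites (default BTN, GL).
#' @param years Integer vector of sampling years (default 2007:2008).
#' @param n_colonies_per_site Colonies per main site (default 6; colonies
#'   persist across years).
#' @param morph_site Optional extra site where both colony morphologies
#'   co-occur (default `"PR"`, sampled in the last year only; set to `NULL`
#'   to skip).
#' @param n_colonies_per_morph Colonies per morphology at `morph_site`
#'   (default 3).
#' @param library_size_range Clones per library, inclusive range (default
#'   `c(7, 13)`).
#' @param egg_model `"faithful"`, `"shifted"` or `"custom"`.
#' @param egg_mix_weight For `shifted`/`custom`: weight on the clade-C
#'   profile mixed into the egg composition of clade-D-dominated parents
#'   (default 0.6).
#' @param overdispersion Dirichlet-multinomial concentration scale; larger
#'   means library counts track the colony composition more tightly
#'   (default 15).
#' @param colony_heterogeneity Concentration of the per-colony Dirichlet
#'   draw around the site profile; larger means colonies within a site are
#'   more alike (default 8; very large values make every library a draw
#'   from one shared composition).
#' @param site_d_weight Proportion of clade D in the composition profile of
#'   the first main site (default 0.8; remaining sites get 0.1).
#' @param pseudogene_labels Labels of injected pseudogene-flagged satellite
#'   variants (default none).
#' @return A `sim_config` list.
#' @export
sim_config <- function(aligned_length = 320L,
                       dominants_per_clade = c(C = 3L, D = 2L),
                       satellites_per_dominant = 3L,
                       variant_edit_range = c(1L, 3L),
                       interclade_divergence = 0.25,
                       sites = c("BTN", "GL"),
                       years = 2007:2008,
                       n_colonies_per_site = 6L,
                       morph_site = "PR",
                       n_colonies_per_morph = 3L,
                       library_size_range = c(7L, 13L),
                       egg_model = c("faithful", "shifted", "custom"),
                       egg_mix_weight = 0.6,
                       overdispersion = 15,
                       colony_heterogeneity = 8,
                       site_d_weight = 0.8,
                       pseudogene_labels = character()) {
  egg_model <- match.arg(egg_model)
  stopifnot(aligned_length >= 10,
            all(variant_edit_range >= 1),
            variant_edit_range[1] <= variant_edit_range[2],
            interclade_divergence > 0, interclade_divergence <= 1,
            library_size_range[1] >= 1,
            library_size_range[1] <= library_size_range[2],
            egg_mix_weight >= 0, egg_mix_weight <= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(m) {
  paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, n_edits) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_edits)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(sequence = paste(chars, collapse = ""), positions = sort(pos))
}

#' Generate a synthetic variant set
#'
#' Two clade ancestors at the configured divergence, dominant haplotypes a
#' few substitutions from their ancestor, and satellites exactly 1-3
#' substitutions from a recorded dominant. The truth record stores every
#' edit so tests can recompute distances independently.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `variants` (variant tibble) and `truth` (tibble:
#'   `label`, `parent`, `n_edits`).
#' @export
make_variants <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- config$aligned_length
  anc <- list(C = random_seq(m))
  n_div <- max(1L, round(config$interclade_divergence * m))
  anc$D <- mutate_seq(anc$C, n_div)$sequence

  rows <- list()
  truth <- list()
  for (clade in names(config$dominants_per_clade)) {
    nd <- config$dominants_per_clade[[clade]]
    for (d in seq_len(nd)) {
      dom_label <- paste0(clade, d)
      dom_seq <- if (d == 1) anc[[clade]] else
        mutate_seq(anc[[clade]], sample(3:5, 1))$sequence
      rows[[dom_label]] <- tibble(
        label = dom_label, clade = clade, sequence = dom_seq,
        published = TRUE, pseudogene = FALSE)
      truth[[dom_label]] <- tibble(label = dom_label,
                                   parent = NA_character_, n_edits = NA_integer_)
      for (s in seq_len(config$satellites_per_dominant)) {
        lab <- paste0(dom_label, ".", s)
        k <- sample(seq(config$variant_edit_range[1],
                        config$variant_edit_range[2]), 1)
        mut <- mutate_seq(dom_seq, k)
        rows[[lab]] <- tibble(
          label = lab, clade = clade, sequence = mut$sequence,
          published = FALSE,
          pseudogene = lab %in% config$pseudogene_labels)
        truth[[lab]] <- tibble(label = lab, parent = dom_label,
                               n_edits = k)
      }
    }
  }
  list(variants = as_variant_table(bind_rows(rows)),
       truth = bind_rows(truth))
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a complete dataset bundle
#'
#' Per colony, an adult composition is drawn from a site-dependent
#' Dirichlet profile (one main site clade-D-rich, the others clade-C-rich);
#' clone libraries are Dirichlet-multinomial draws of 7-13 clones; eggs
#' follow the configured egg model. Metadata covers both built-in designs
#' (site/year/life stage/colony, plus a morphology site).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @return A list: `bundle` (a [sym_bundle()]), `truth` (list with the
#'   variant edit record and per-colony mixing weights).
#' @export
simulate_bundle <- function(config, seed = 1L) {
  if (config$n_colonies_per_site < 1) abort("n_colonies_per_site must be >= 1")
  mv <- make_variants(config, seed = seed)
  variants <- mv$variants
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  is_d <- variants$clade == "D"
  profile_for <- function(d_weight) {
    w <- ifelse(is_d, d_weight / max(sum(is_d), 1),
                (1 - d_weight) / max(sum(!is_d), 1))
    w / sum(w)
  }
  c_profile <- profile_for(0.02)

  units <- list()
  for (s in seq_along(config$sites)) {
    for (co in seq_len(config$n_colonies_per_site)) {
      units[[length(units) + 1]] <- list(
        site = config$sites[s],
        colony = paste0(config$sites[s], "_c", co),
        years = config$years,
        morph = "unknown",
        d_weight = if (s == 1) config$site_d_weight else 0.1)
    }
  }
  if (!is.null(config$morph_site)) {
    for (mo in c("branching", "plating")) {
      for (co in seq_len(config$n_colonies_per_morph)) {
        units[[length(units) + 1]] <- list(
          site = config$morph_site,
          colony = paste0(config$morph_site, "_", substr(mo, 1, 1), co),
          years = max(config$years),
          morph = mo,
          d_weight = 0.3)
      }
    }
  }

  draw_library <- function(weights, size) {
    p <- rdirichlet1(config$overdispersion * weights +
                       1e-8 * (weights > 0))
    as.integer(rmultinom(1, size, p))
  }
  lib_size <- function() {
    sample(seq(config$library_size_range[1],
               config$library_size_range[2]), 1)
  }

  libs <- list()
  weights_truth <- list()
  for (u in units) {
    for (yr in u$years) {
      adult_w <- rdirichlet1(config$colony_heterogeneity *
                               profile_for(u$d_weight))
      egg_w <- switch(
        config$egg_model,
        faithful = adult_w,
        shifted = ,
        custom = {
          d_dom <- sum(adult_w[is_d]) > 0.5
          if (d_dom) {
            config$egg_mix_weight * c_profile +
              (1 - config$egg_mix_weight) * adult_w
          } else adult_w
        })
      for (stage in c("adult", "egg")) {
        w <- if (stage == "adult") adult_w else egg_w
        counts <- draw_library(w, lib_size())
        keep <- counts > 0
        sid <- paste(u$site, yr, u$colony, stage, sep = "_")
        libs[[sid]] <- tibble(
          sample_id = sid, variant = variants$label[keep],
          count = counts[keep], colony_id = u$colony, site = u$site,
          year = yr, life_stage = stage, morphology = u$morph)
        weights_truth[[sid]] <- tibble(
          sample_id = sid, variant = variants$label, weight = w)
      }
    }
  }
  libraries <- bind_rows(libs)
  bundle <- sym_bundle(variants, libraries)
  list(bundle = bundle,
       truth = list(variants = mv$truth,
                    weights = bind_rows(weights_truth)))
}
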