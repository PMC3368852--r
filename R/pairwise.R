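#' Percent similarity index between two clone libraries
#'
#' Renkonen/Wolda index on relative clone abundances:
#' \deqn{PSI = \sum_{v} \min(p_v, q_v)}
#' over variants shared by the two libraries, where `p` and `q` are the
#' relative abundances in each library. 0 means no shared variants, 1 means
#' identical composition. Symmetric and invariant to rescaling the counts of
#' either library.
#'
#' @param counts_a,counts_b Named numeric vectors of clone counts, or
#'   two-column data frames (`variant`, `count`).
#' @return PSI as a proportion in `[0, 1]`.
#' @examples
#' psi(c(D1a = 7, D1 = 1, D1a.1 = 1), c(D1a = 5, D1a.1 = 3, D1 = 2))
#' @export
psi <- function(counts_a, counts_b) {
  a <- as_count_vector(counts_a)
  b <- as_count_vector(counts_b)
  if (sum(a) == 0 || sum(b) == 0) {
    abort("cannot compute PSI on empty library")
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) return(0)
  sum(pmin(a[shared] / sum(a), b[shared] / sum(b)))
}

as_count_vector <- function(x) {
  if (is.data.frame(x)) {
    v <- x$count
    names(v) <- x$variant
    return(v)
  }
  if (is.null(names(x))) abort("counts must be named by variant")
  x
}

#' Two-group AMOVA on a clone distance matrix
#'
#' Distance formulation of the analysis of molecular variance for two
#' groups of clones (e.g. the adult and egg libraries of one colony). With
#' squared inter-clone distances \eqn{d^2_{ij}}:
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},}
#' \eqn{SS_{among} = SS_{total} - SS_{within}}; variance components follow
#' the standard expectations with
#' \eqn{n_0 = (N - \sum_g n_g^2/N)/(k-1)}, and
#' \eqn{\Phi = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}. \eqn{\Phi} is 0 for
#' identical composition, 1 under alternate fixation, and may be negative
#' (no truncation is applied). If both components are 0 the result is
#' degenerate and \eqn{\Phi = 0}.
#'
#' @param d Square symmetric matrix of clone-clone distances (raw
#'   differences; they are squared internally).
#' @param group Vector of group labels, one per row of `d`; exactly two
#'   distinct values with at least one clone each.
#' @return A `sym_pair_amova` list: `phi`, `sigma2_among`, `sigma2_within`,
#'   `ss_among`, `ss_within`, `df`, plus `p_value = NA` until
#'   [permutation_test()] fills it.
#' @export
pairwise_phi <- function(d, group) {
  d <- unclass(d)
  stopifnot(nrow(d) == length(group))
  group <- as.character(group)
  g <- unique(group)
  if (length(g) != 2) abort("pairwise_phi needs exactly two groups")
  if (any(table(group) == 0)) abort("a group has size 0")
  comp <- amova2_components(d^2, group)
  structure(
    c(comp, list(p_value = NA_real_, n_permutations = 0L, seed = NA_integer_)),
    class = "sym_pair_amova")
}

# shared core: squared-distance matrix -> components (k groups, k = 2 used)
amova2_components <- function(d2, group) {
  n_tot <- nrow(d2)
  groups <- split(seq_len(n_tot), group)
  k <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n_tot
  ss_within <- sum(vapply(groups, function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  n_g <- lengths(groups)
  n0 <- (n_tot - sum(n_g^2) / n_tot) / (k - 1)
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (n_tot - k)
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0
  denom <- sigma2_among + sigma2_within
  phi <- if (denom > 0) sigma2_among / denom else 0
  list(phi = phi, sigma2_among = sigma2_among,
       sigma2_within = sigma2_within,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       df = c(among = k - 1, within = n_tot - k))
}

#' Permutation test for the two-group AMOVA
#'
#' Clones are permuted between the two groups keeping group sizes fixed;
#' the p-value uses the add-one rule
#' \eqn{p = (1 + \#\{\Phi^* \ge \Phi_{obs}\}) / (1 + n_{perm})} so it is
#' never exactly 0.
#'
#' @inheritParams pairwise_phi
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; recorded in the result.
#' @return A `sym_pair_amova` with `p_value`, `n_permutations`, `seed`
#'   filled in.
#' @export
permutation_test <- function(d, group, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 1)
  obs <- pairwise_phi(d, group)
  d2 <- unclass(d)^2
  n <- nrow(d2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    phi_b <- amova2_components(d2, group[perm])$phi
    if (phi_b >= obs$phi - 1e-12) hits <- hits + 1L
  }
  obs$p_value <- (1 + hits) / (1 + n_perm)
  obs$n_permutations <- as.integer(n_perm)
  obs$seed <- as.integer(seed)
  obs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sym_pair_amova <- function(x, ...) {
  cat("<sym_pair_amova> Phi = ", signif(x$phi, 4), sep = "")
  if (!is.na(x$p_value)) {
    cat(", p = ", signif(x$p_value, 3), " (", x$n_permutations,
        " permutations)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.sym_pair_amova <- function(x, ...) {
  tibble(
    term = c("among_groups", "within_groups"),
    df = unname(x$df),
    sumsq = c(x$ss_among, x$ss_within),
    sigma2 = c(x$sigma2_among, x$sigma2_within))
}

#' @export
glance.sym_pair_amova <- function(x, ...) {
  tibble(phi = x$phi, p_value = x$p_value,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' Per-colony adult-vs-egg statistics
#'
#' For each colony x year with both life stages present, computes the
#' number of clades per library, PSI between adult and egg, and (optionally)
#' the two-group AMOVA Phi with its permutation p-value.
#'
#' @param libraries Screened library tibble.
#' @param variants Variant tibble (for clades and, when `phi = TRUE`,
#'   sequences).
#' @param phi Compute per-colony Phi and permutation p? (Requires real
#'   sequences; PSI only needs counts.)
#' @param gap_mode Gap handling for the distance matrix when `phi = TRUE`.
#' @param n_perm,seed Permutation settings when `phi = TRUE`.
#' @return A tibble with one row per colony x year: `site`, `year`,
#'   `colony_id`, `s_adult`, `s_egg`, `psi`, and when requested `phi`, `p`.
#' @examples
#' b <- table1_fixture()
#' libs <- apply_screen(b$libraries, screen_variants(b$libraries, b$variants))
#' pair_stats(libs, b$variants)
#' @export
pair_stats <- function(libraries, variants, phi = FALSE,
                       gap_mode = "fifth_state", n_perm = 999L, seed = 1L) {
  vd <- if (phi) variant_distance_matrix(variants, gap_mode) else NULL
  keys <- distinct(libraries[, c("site", "year", "colony_id")])
  rows <- pmap(keys, function(site, year, colony_id) {
    sub <- filter(libraries, .data$site == !!site, .data$year == !!year,
                  .data$colony_id == !!colony_id)
    ad <- filter(sub, .data$life_stage == "adult")
    eg <- filter(sub, .data$life_stage == "egg")
    if (nrow(ad) == 0 || nrow(eg) == 0) return(NULL)
    out <- tibble(
      site = site, year = year, colony_id = colony_id,
      s_adult = dplyr::n_distinct(
        variants$clade[match(ad$variant, variants$label)]),
      s_egg = dplyr::n_distinct(
        variants$clade[match(eg$variant, variants$label)]),
      psi = psi(ad, eg))
    if (phi) {
      cd <- clone_distance_matrix(sub, vd)
      res <- permutation_test(cd$d, cd$clones$life_stage,
                              n_perm = n_perm, seed = seed)
      out$phi <- res$phi
      out$p <- res$p_value
    }
    out
  })
  bind_rows(rows)
}
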