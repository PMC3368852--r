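# Independent brute-force oracles used to pin expected values. These are
# deliberately written as explicit loops over pairs, independent of the
# package's matrix-based implementations.

# two-group AMOVA by explicit double loops over clone pairs
oracle_pair_amova <- function(d, group) {
  n <- nrow(d)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ss_total <- ss_total + d[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(group)) {
    idx <- which(group == g)
    acc <- 0
    if (length(idx) >= 2) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + d[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  k <- length(unique(group))
  n_g <- as.numeric(table(group))
  n0 <- (n - sum(n_g^2) / n) / (k - 1)
  ms_a <- ss_among / (k - 1)
  ms_w <- ss_within / (n - k)
  s2w <- ms_w
  s2a <- (ms_a - ms_w) / n0
  phi <- if (s2a + s2w > 0) s2a / (s2a + s2w) else 0
  list(phi = phi, sigma2_among = s2a, sigma2_within = s2w,
       ss_among = ss_among, ss_within = ss_within)
}

# four-level diploid AMOVA by explicit loops over allele-copy pairs
oracle_hier_amova <- function(ind, allele_dist) {
  copies <- data.frame(
    allele = c(ind$allele_a, ind$allele_b),
    individual = rep(ind$individual_id, 2),
    sample = rep(paste(ind$group, ind$sample), 2),
    group = rep(ind$group, 2),
    stringsAsFactors = FALSE)
  C <- nrow(copies)
  d2 <- function(i, j) allele_dist[copies$allele[i], copies$allele[j]]^2
  ss_set <- function(idx) {
    acc <- 0
    if (length(idx) >= 2) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + d2(idx[a], idx[b])
      }
    }
    acc / length(idx)
  }
  ss_total <- ss_set(seq_len(C))
  ss_wi <- sum(sapply(unique(copies$individual),
                      function(x) ss_set(which(copies$individual == x))))
  ss_ws <- sum(sapply(unique(copies$sample),
                      function(x) ss_set(which(copies$sample == x))))
  ss_wg <- sum(sapply(unique(copies$group),
                      function(x) ss_set(which(copies$group == x))))
  list(ss_among_groups = ss_total - ss_wg,
       ss_among_samples = ss_wg - ss_ws,
       ss_among_individuals = ss_ws - ss_wi,
       ss_within_individuals = ss_wi)
}

# total SS of a centered matrix by explicit double loop
oracle_trace_ss <- function(d) {
  n <- nrow(d)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) acc <- acc + d[i, j]^2
  acc / n
}

# small random variant set + two libraries for property suites
random_toy_libraries <- function(n_variants = 4, max_clones = 10,
                                 max_dist = 8) {
  labs <- paste0("h", seq_len(n_variants))
  d <- matrix(0, n_variants, n_variants, dimnames = list(labs, labs))
  for (i in seq_len(n_variants - 1)) for (j in (i + 1):n_variants) {
    d[i, j] <- d[j, i] <- sample.int(max_dist, 1)
  }
  n_a <- sample(2:max_clones, 1)
  n_b <- sample(2:max_clones, 1)
  clone_a <- sample(labs, n_a, replace = TRUE)
  clone_b <- sample(labs, n_b, replace = TRUE)
  clones <- c(clone_a, clone_b)
  list(d = d[clones, clones],
       group = rep(c("a", "b"), c(n_a, n_b)),
       labels = clones)
}

# random diploid genotype table plus allele distance matrix
toy_genotypes <- function(seed = 1, n_ind = 12, n_alleles = 5,
                          n_groups = 2, samples_per_group = 2) {
  withr::with_seed(seed, {
    alle <- paste0("a", seq_len(n_alleles))
    d <- matrix(0, n_alleles, n_alleles, dimnames = list(alle, alle))
    d[upper.tri(d)] <- sample.int(6, sum(upper.tri(d)), replace = TRUE)
    d <- d + t(d)
    groups <- rep(paste0("g", seq_len(n_groups)), length.out = n_ind)
    list(
      individuals = tibble::tibble(
        individual_id = paste0("i", seq_len(n_ind)),
        allele_a = sample(alle, n_ind, TRUE),
        allele_b = sample(alle, n_ind, TRUE),
        group = sort(groups),
        sample = paste0("s", rep_len(seq_len(samples_per_group),
                                     n_ind))),
      allele_dist = d)
  })
}

# drop distance-object attributes, keep the bare matrix
strip_dist <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# wrap a plain matrix as a raw-differences distance object
new_sym_dist_for_test <- function(m) {
  structure(m, metric = "raw_differences",
            class = c("sym_dist", "matrix", "array"))
}

# printed per-colony PSI column (site, year, colony -> value), half-up 2 dp
printed_psi <- function() {
  c("BTN_1_2007" = 0.50, "BTN_8_2007" = 0.22, "BTN_10_2007" = 0.00,
    "BTN_11_2007" = 0.72, "BTN_12_2007" = 0.10, "BTN_18_2007" = 0.00,
    "BTN_19_2007" = 0.38, "BTN_8_2008" = 0.11, "BTN_10_2008" = 0.69,
    "BTN_19_2008" = 0.30, "GL_23_2007" = 0.65, "GL_29_2007" = 0.63,
    "GL_30_2007" = 0.45, "GL_35_2007" = 0.86, "GL_36_2007" = 0.50,
    "GL_37_2007" = 0.10, "GL_39_2007" = 0.73, "GL_23_2008" = 0.14,
    "GL_29_2008" = 0.88, "GL_37_2008" = 0.38, "PR_B1_2008" = 0.27,
    "PR_B2_2008" = 0.45, "PR_B5_2008" = 0.73, "PR_B6_2008" = 0.20,
    "PR_B7_2008" = 0.36, "PR_B8_2008" = 0.24, "PR_P1_2008" = 0.27,
    "PR_P2_2008" = 0.64, "PR_P5_2008" = 0.00, "PR_P6_2008" = 0.64,
    "PR_P7_2008" = 0.54, "PR_P9_2008" = 0.55)
}

# round half away from zero at 2 dp (the convention of the printed table)
round2up <- function(x) floor(x * 100 + 0.5) / 100

# screened per-colony PSI table from the printed-count fixture
fixture_psi_table <- function() {
  b <- table1_fixture()
  screen <- screen_variants(b$libraries, b$variants)
  libs <- apply_screen(b$libraries, screen)
  pair_stats(libs, b$variants, phi = FALSE)
}
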