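#' Hierarchical diploid AMOVA on host genotypes
#'
#' Four-level analysis of molecular variance for diploid nuclear genotypes
#' (two allele copies per individual) under an explicit two-level grouping
#' hierarchy: groups (e.g. morphology or collection site) > samples >
#' individuals > allele copies. Sums of squares use the distance
#' formulation on squared allele distances over the 2N allele copies;
#' variance components come from the standard nested expectations with
#' unbalanced-size coefficients, and the Phi statistics are the usual
#' ratios:
#' \itemize{
#'   \item `among_groups`: \eqn{\Phi_{AM} = \sigma^2_a / \sigma^2_T}
#'   \item `among_samples_within_groups`:
#'     \eqn{\Phi_{AS(AM)} = \sigma^2_b / (\sigma^2_b+\sigma^2_c+\sigma^2_d)}
#'   \item `among_individuals_within_samples`:
#'     \eqn{\Phi_{AI} = \sigma^2_c / (\sigma^2_c+\sigma^2_d)}
#'   \item `within_individuals`:
#'     \eqn{\Phi_{WI} = (\sigma^2_a+\sigma^2_b+\sigma^2_c)/\sigma^2_T}
#' }
#' Negative components are reported as-is. If every allele copy is
#' identical the result is degenerate-flagged with all Phi set to 0.
#'
#' @param individuals Tibble with columns `individual_id`, `allele_a`,
#'   `allele_b`, `group`, `sample` — two allele labels per individual and
#'   the two-level hierarchy.
#' @param allele_dist Named symmetric matrix of allele-allele distances
#'   (e.g. Hamming differences on the aligned intron). Alternatively pass
#'   `allele_seqs`.
#' @param allele_seqs Named character vector of aligned allele sequences;
#'   distances are computed as Hamming differences (gaps fifth state).
#' @param n_perm Permutations per level (0 to skip tests).
#' @param seed Integer seed.
#' @return A `sym_hier_amova`; `tidy()` gives one row per level with df,
#'   SS, variance component, percent of variation, Phi and permutation p.
#' @export
hier_amova <- function(individuals, allele_dist = NULL, allele_seqs = NULL,
                       n_perm = 999L, seed = 1L) {
  ind <- as_tibble(individuals)
  need <- c("individual_id", "allele_a", "allele_b", "group", "sample")
  miss <- setdiff(need, names(ind))
  if (length(miss) > 0) {
    abort(paste0("individuals missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(is.na(ind$allele_a) | is.na(ind$allele_b))) {
    abort("individual with missing allele")
  }
  if (dplyr::n_distinct(ind$group) < 2) abort("need >= 2 groups")

  if (is.null(allele_dist)) {
    if (is.null(allele_seqs)) abort("supply allele_dist or allele_seqs")
    av <- as_variant_table(tibble(label = names(allele_seqs),
                                  sequence = unname(allele_seqs)))
    allele_dist <- unclass(variant_distance_matrix(av))
  }
  alleles <- unique(c(ind$allele_a, ind$allele_b))
  missd <- setdiff(alleles, rownames(allele_dist))
  if (length(missd) > 0) {
    abort(paste0("allele absent from distance matrix: ",
                 paste(missd, collapse = ", ")))
  }
  singleton <- summarise(group_by(ind, .data$group, .data$sample),
                         n = n(), .groups = "drop")
  flag_singleton <- any(singleton$n == 1)

  # copy-level layout: 2 copies per individual
  copies <- tibble(
    allele = c(ind$allele_a, ind$allele_b),
    individual = rep(ind$individual_id, 2),
    sample = rep(paste(ind$group, ind$sample, sep = "\r"), 2),
    group = rep(ind$group, 2))
  d2 <- allele_dist[copies$allele, copies$allele]^2

  obs <- hier_components(d2, copies)
  res <- obs$table
  res$p_perm <- NA_real_
  if (n_perm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    hits <- numeric(4)
    n_ind <- nrow(ind)
    for (b in seq_len(n_perm)) {
      # level 1: whole samples among groups
      samp_tab <- distinct(copies[, c("sample", "group")])
      g_perm <- samp_tab$group[sample.int(nrow(samp_tab))]
      c1 <- copies
      c1$group <- g_perm[match(copies$sample, samp_tab$sample)]
      phi1 <- hier_components(d2, c1)$table$phi[1]
      # level 2: individuals among samples within groups
      c2 <- copies
      new_sample <- ind_permute_within(ind, "sample")
      c2$sample <- paste(rep(ind$group, 2), rep(new_sample, 2), sep = "\r")
      phi2 <- hier_components(d2, c2)$table$phi[2]
      # level 3: allele copies among individuals within samples
      c3 <- copies
      c3$individual <- permute_within(copies$individual, copies$sample)
      phi3 <- hier_components(d2, c3)$table$phi[3]
      # level 4: allele copies among all individuals
      c4 <- copies
      c4$individual <- copies$individual[sample.int(nrow(copies))]
      phi4 <- hier_components(d2, c4)$table$phi[4]
      hits <- hits + (c(phi1, phi2, phi3, phi4) >= res$phi - 1e-12)
    }
    res$p_perm <- (1 + hits) / (1 + n_perm)
  }
  structure(list(table = res, degenerate = obs$degenerate,
                 singleton_samples = flag_singleton,
                 n_individuals = nrow(ind), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "sym_hier_amova")
}

# permute a copy-level label vector within strata
permute_within <- function(x, strata) {
  idx <- seq_along(x)
  for (s in unique(strata)) {
    k <- which(strata == s)
    x[k] <- x[k][sample.int(length(k))]
  }
  x
}

# permute individuals' sample assignment within their group
ind_permute_within <- function(ind, col) {
  out <- ind[[col]]
  for (g in unique(ind$group)) {
    k <- which(ind$group == g)
    out[k] <- out[k][sample.int(length(k))]
  }
  out
}

# SS decomposition + components for the 4-level diploid layout
hier_components <- function(d2, copies) {
  C <- nrow(d2)
  ss_in <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_total <- sum(d2[upper.tri(d2)]) / C
  by_ind <- split(seq_len(C), copies$individual)
  by_samp <- split(seq_len(C), copies$sample)
  by_grp <- split(seq_len(C), copies$group)
  ss_wi <- sum(vapply(by_ind, ss_in, numeric(1)))
  ss_ws <- sum(vapply(by_samp, ss_in, numeric(1)))
  ss_wg <- sum(vapply(by_grp, ss_in, numeric(1)))
  ss_ai <- ss_ws - ss_wi
  ss_as <- ss_wg - ss_ws
  ss_ag <- ss_total - ss_wg

  n_ind <- length(by_ind)
  n_samp <- length(by_samp)
  n_grp <- length(by_grp)
  df <- c(n_grp - 1, n_samp - n_grp, n_ind - n_samp, n_ind)
  ms <- c(ss_ag, ss_as, ss_ai, ss_wi) / df

  # unbalanced-size coefficients (allele-copy counts)
  c_s <- lengths(by_samp)
  c_g <- lengths(by_grp)
  grp_of_samp <- copies$group[match(names(by_samp),
                                    copies$sample)]
  A <- sum(c_s^2 / c_g[grp_of_samp])
  B <- sum(c_s^2) / C
  D <- sum(c_g^2) / C
  n1 <- (C - A) / (n_samp - n_grp)
  n2 <- (A - B) / (n_grp - 1)
  n3 <- (C - D) / (n_grp - 1)

  s_wi <- ms[4]
  s_ai <- (ms[3] - ms[4]) / 2
  s_as <- (ms[2] - ms[3]) / n1
  s_ag <- (ms[1] - ms[3] - n2 * s_as) / n3
  comp <- c(s_ag, s_as, s_ai, s_wi)
  total <- sum(comp)
  degenerate <- !is.finite(total) || abs(total) < 1e-14
  if (degenerate) {
    phi <- rep(0, 4)
    pct <- rep(0, 4)
  } else {
    phi <- c(
      s_ag / total,
      s_as / (s_as + s_ai + s_wi),
      s_ai / (s_ai + s_wi),
      (s_ag + s_as + s_ai) / total)
    pct <- 100 * comp / total
  }
  list(table = tibble(
    level = c("among_groups", "among_samples_within_groups",
              "among_individuals_within_samples", "within_individuals"),
    df = df,
    sumsq = c(ss_ag, ss_as, ss_ai, ss_wi),
    sigma2 = comp,
    pct_variation = pct,
    phi = phi),
    degenerate = degenerate)
}

#' @export
print.sym_hier_amova <- function(x, ...) {
  cat("<sym_hier_amova> ", x$n_individuals, " individuals",
      if (x$degenerate) " [degenerate: no variation]", "\n", sep = "")
  if (x$singleton_samples) cat("  note: a sample holds one individual\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.sym_hier_amova <- function(x, ...) x$table

#' @export
glance.sym_hier_amova <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, degenerate = x$degenerate,
         n_permutations = x$n_perm, seed = x$seed)
}

#' Exact test of population non-differentiation
#'
#' Tests homogeneity of an allele x population contingency table by the
#' probability of the observed table conditional on its margins. For small
#' tables (total count at most `enumerate_limit`) the p-value is the exact
#' sum of the conditional probabilities of every fixed-margin table no more
#' probable than the observed one. Larger tables use a Markov chain over
#' fixed-margin tables with 2x2 switch proposals (Metropolis acceptance on
#' the conditional probability), estimating the same tail probability.
#'
#' @param tab Matrix of non-negative integer counts (alleles x populations)
#'   with all row and column margins >= 1.
#' @param chain_steps Markov chain length for the chain estimate.
#' @param burn_in Steps discarded before counting.
#' @param seed Integer seed for the chain.
#' @param enumerate_limit Total-count threshold below which complete
#'   enumeration is used.
#' @return A `sym_exact_test` list: `p_value`, `method`
#'   (`"enumeration"`/`"chain"`), `chain_steps`, `seed`, `table_dim`.
#' @export
exact_test <- function(tab, chain_steps = 10000L, burn_in = 1000L,
                       seed = 1L, enumerate_limit = 12L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("table must hold non-negative integers")
  }
  if (any(rowSums(tab) < 1) || any(colSums(tab) < 1)) {
    abort("zero margin in contingency table")
  }
  storage.mode(tab) <- "integer"
  lp_obs <- table_log_prob(tab)
  if (sum(tab) <= enumerate_limit) {
    all_lp <- enumerate_tables_logprob(rowSums(tab), colSums(tab))
    p <- sum(exp(all_lp[all_lp <= lp_obs + 1e-9]))
    out <- list(p_value = min(p, 1), method = "enumeration",
                chain_steps = 0L, seed = NA_integer_, table_dim = dim(tab))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cur <- tab
    lp_cur <- lp_obs
    hits <- 0L
    counted <- 0L
    nr <- nrow(tab); nc <- ncol(tab)
    for (step in seq_len(chain_steps + burn_in)) {
      i <- sample.int(nr, 2)
      j <- sample.int(nc, 2)
      dir <- if (runif(1) < 0.5) 1L else -1L
      a <- cur[i[1], j[1]] + dir; b <- cur[i[1], j[2]] - dir
      c2 <- cur[i[2], j[1]] - dir; e <- cur[i[2], j[2]] + dir
      if (min(a, b, c2, e) >= 0) {
        # probability ratio of the switched table
        if (dir == 1L) {
          lr <- log(cur[i[1], j[2]]) + log(cur[i[2], j[1]]) -
            log(cur[i[1], j[1]] + 1) - log(cur[i[2], j[2]] + 1)
        } else {
          lr <- log(cur[i[1], j[1]]) + log(cur[i[2], j[2]]) -
            log(cur[i[1], j[2]] + 1) - log(cur[i[2], j[1]] + 1)
        }
        if (log(runif(1)) < lr) {
          cur[i[1], j[1]] <- a; cur[i[1], j[2]] <- b
          cur[i[2], j[1]] <- c2; cur[i[2], j[2]] <- e
          lp_cur <- lp_cur + lr
        }
      }
      if (step > burn_in) {
        counted <- counted + 1L
        if (lp_cur <= lp_obs + 1e-9) hits <- hits + 1L
      }
    }
    out <- list(p_value = (1 + hits) / (1 + counted), method = "chain",
                chain_steps = as.integer(chain_steps),
                seed = as.integer(seed), table_dim = dim(tab))
  }
  structure(out, class = "sym_exact_test")
}

# log conditional probability of a fixed-margin table
table_log_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# log-probabilities of every table with the given margins (small totals)
enumerate_tables_logprob <- function(rs, cs) {
  nr <- length(rs)
  out <- numeric(0)
  recurse <- function(rows_left, cs_left, acc_lp) {
    if (length(rows_left) == 1) {
      if (any(cs_left < 0)) return()
      out[[length(out) + 1]] <<- acc_lp - sum(lgamma(cs_left + 1))
      return()
    }
    r <- rows_left[1]
    for (cells in compositions(r, cs_left)) {
      recurse(rows_left[-1], cs_left - cells,
              acc_lp - sum(lgamma(cells + 1)))
    }
  }
  base <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
  recurse(rs, cs, base)
  out
}

# all ways to split total r over cells bounded by caps
compositions <- function(r, caps) {
  k <- length(caps)
  if (k == 1) {
    if (r <= caps) return(list(r)) else return(list())
  }
  res <- list()
  for (x in 0:min(r, caps[1])) {
    for (rest in compositions(r - x, caps[-1])) {
      res[[length(res) + 1]] <- c(x, rest)
    }
  }
  res
}

#' @export
print.sym_exact_test <- function(x, ...) {
  cat("<sym_exact_test> p = ", signif(x$p_value, 4), " (", x$method,
      if (x$method == "chain") paste0(", ", x$chain_steps, " steps"),
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.sym_exact_test <- function(x, ...) {
  tibble(p_value = x$p_value, method = x$method,
         chain_steps = x$chain_steps,
         n_alleles = x$table_dim[1], n_populations = x$table_dim[2])
}
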