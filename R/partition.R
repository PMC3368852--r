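#' Gower-centered inner-product matrix
#'
#' The McArdle-Anderson machinery behind distance-based partitioning:
#' \deqn{G = -\tfrac{1}{2} J D^{(2)} J, \qquad J = I - \mathbf{1}\mathbf{1}'/n,}
#' where \eqn{D^{(2)}} holds squared distances. `trace(G)` equals the total
#' sum of squares \eqn{(1/n)\sum_{i<j} d^2_{ij}}.
#'
#' @param d Square symmetric distance matrix (a `sym_dist`, typically
#'   sqrt-transformed clone distances).
#' @return The centered matrix `G` (plain matrix).
#' @export
gower_center <- function(d) {
  d <- unclass(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Model designs for the multifactor partition
#'
#' A design is an ordered list of model terms fitted sequentially (Type I
#' sums of squares in the stated order). Each term is written with `:` for
#' crossing and `%in%` for nesting, over the factor columns of the clone
#' table, e.g. `"colony_id %in% site"` or `"year:life_stage"`.
#'
#' @param terms Character vector of term strings, in fitting order.
#' @param n_permutations Number of permutations for the per-term tests.
#' @param permute Permutable units: `"clone"` (unrestricted permutation of
#'   clones, the default approximation) or `"library"` (permute whole
#'   libraries, keeping clones of a sample together).
#' @param seed Integer seed.
#' @return A `sym_design` list.
#' @export
sym_design <- function(terms, n_permutations = 10000L,
                       permute = c("clone", "library"), seed = 1L) {
  permute <- match.arg(permute)
  structure(list(terms = terms, n_permutations = as.integer(n_permutations),
                 permute = permute, seed = as.integer(seed)),
            class = "sym_design")
}

#' Ready-made published-style designs
#'
#' Returns the two nested multifactor designs used for parent/egg clone
#' libraries: a four-factor design (site, year, life stage, colony nested
#' in site, and all their admissible interactions — 11 non-residual terms)
#' for the two sites sampled in both years, and a three-factor design
#' (morphology, life stage, colony nested in morphology — 5 non-residual
#' terms) for the site where both colony morphologies co-occur.
#'
#' @param n_permutations Permutations per term (default 10000).
#' @param seed Integer seed.
#' @return A list with elements `four_factor` and `three_factor`, each a
#'   [sym_design()].
#' @export
builtin_designs <- function(n_permutations = 10000L, seed = 1L) {
  four <- c(
    "site", "year", "life_stage", "colony_id %in% site",
    "site:year", "site:life_stage", "year:life_stage",
    "year:(colony_id %in% site)", "life_stage:(colony_id %in% site)",
    "site:year:life_stage", "year:life_stage:(colony_id %in% site)")
  three <- c(
    "morphology", "life_stage", "colony_id %in% morphology",
    "morphology:life_stage", "life_stage:(colony_id %in% morphology)")
  list(four_factor = sym_design(four, n_permutations, seed = seed),
       three_factor = sym_design(three, n_permutations, seed = seed))
}

# factors participating in a term string
term_factors <- function(term) {
  x <- gsub("%in%", ":", term, fixed = TRUE)
  x <- gsub("[() ]", "", x)
  setdiff(unique(strsplit(x, ":", fixed = TRUE)[[1]]), "")
}

# grouping factor for a term: interaction of all participating factors
term_grouping <- function(term, data) {
  fac <- term_factors(term)
  miss <- setdiff(fac, names(data))
  if (length(miss) > 0) {
    abort(paste0("term '", term, "' references unknown factor(s): ",
                 paste(miss, collapse = ", ")))
  }
  interaction(lapply(fac, function(f) factor(data[[f]])), drop = TRUE)
}

#' Fit a nested multifactor distance partition
#'
#' Sequential (Type I) partition of the total sum of squares of a clone
#' distance matrix onto the model terms of a design, with pseudo-F per term
#' against the residual mean square (by default) and permutation p-values.
#' This is the McArdle-Anderson projection approach: each term contributes
#' \eqn{SS = tr((H_k - H_{k-1}) G)} where \eqn{H_k} projects onto the
#' column space of all terms fitted so far.
#'
#' @param clone_dist A `sym_clone_dist` (clone matrix + factor table), with
#'   the sqrt-transformed metric expected for assemblage data.
#' @param design A [sym_design()].
#' @param denominators Optional named list mapping term -> term whose mean
#'   square should serve as the F denominator instead of the residual
#'   (`"Residual"`); an escape hatch for mixed-model style tests.
#' @return A `sym_partition` object; `tidy()` gives the per-term table
#'   (term, df, SS, MS, phi-like SS ratio, pseudo-F, permutation p).
#' @export
fit_partition <- function(clone_dist, design, denominators = NULL) {
  d <- clone_dist$d
  data <- clone_dist$clones
  if (!identical(attr(d, "metric"), "sqrt_differences")) {
    warn("fit_partition usually expects sqrt-transformed distances")
  }
  G <- gower_center(d)
  n <- nrow(G)
  terms <- design$terms

  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  X <- matrix(1, n, 1)
  r_prev <- 1L
  H_prev <- matrix(1 / n, n, n)
  for (k in seq_along(terms)) {
    g <- term_grouping(terms[k], data)
    X <- cbind(X, stats::model.matrix(~ g - 1))
    qrX <- qr(X)
    r_k <- qrX$rank
    if (r_k == r_prev) {
      abort(paste0("rank-deficient term (confounded with earlier terms): ",
                   terms[k]))
    }
    Q <- qr.Q(qrX)[, seq_len(r_k), drop = FALSE]
    H_k <- tcrossprod(Q)
    hats[[k]] <- H_k - H_prev
    ranks[k] <- r_k - r_prev
    H_prev <- H_k
    r_prev <- r_k
  }
  H_full <- H_prev
  R <- diag(n) - H_full
  df_res <- n - r_prev

  ss_term <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss_res <- sum(R * G)
  ss_total <- sum(diag(G))
  ms_term <- ss_term / ranks
  ms_res <- ss_res / df_res

  denom_ms <- function(k) {
    if (!is.null(denominators) && terms[k] %in% names(denominators)) {
      dt <- denominators[[terms[k]]]
      if (identical(dt, "Residual")) return(ms_res)
      ms_term[match(dt, terms)]
    } else ms_res
  }
  f_term <- vapply(seq_along(terms),
                   function(k) ms_term[k] / denom_ms(k), numeric(1))

  # permutation p per term: permute clone units (or whole libraries)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  nperm <- design$n_permutations
  hits <- numeric(length(terms))
  lib_of <- as.integer(factor(data$sample_id))
  for (b in seq_len(nperm)) {
    perm <- permute_units(n, lib_of, design$permute)
    Gp <- G[perm, perm]
    ssb <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    resb <- sum(R * Gp)
    msb_res <- resb / df_res
    fb <- vapply(seq_along(terms), function(k) {
      den <- if (!is.null(denominators) && terms[k] %in% names(denominators) &&
                 !identical(denominators[[terms[k]]], "Residual")) {
        ssb[match(denominators[[terms[k]]], terms)] /
          ranks[match(denominators[[terms[k]]], terms)]
      } else msb_res
      (ssb[k] / ranks[k]) / den
    }, numeric(1))
    hits <- hits + (fb >= f_term - 1e-12)
  }
  p_perm <- if (nperm > 0) (1 + hits) / (1 + nperm) else rep(NA_real_, length(terms))

  table <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(ranks, df_res, n - 1),
    sumsq = c(ss_term, ss_res, ss_total),
    meansq = c(ms_term, ms_res, NA),
    phi_ss = c(ss_term / ss_total, NA, NA),
    pseudo_f = c(f_term, NA, NA),
    p_perm = c(p_perm, NA, NA))
  structure(list(table = table, design = design, ss_total = ss_total,
                 n = n),
            class = "sym_partition")
}

permute_units <- function(n, lib_of, mode) {
  if (mode == "clone") return(sample.int(n))
  # exchange whole libraries: clones of one library stay together and the
  # library blocks are re-ordered at random (approximate for unequal sizes)
  blocks <- split(seq_len(n), lib_of)
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

#' @export
print.sym_partition <- function(x, ...) {
  cat("<sym_partition> ", x$n, " clones, ",
      sum(!x$table$term %in% c("Residual", "Total")), " terms, ",
      x$design$n_permutations, " permutations\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.sym_partition <- function(x, ...) x$table

#' @export
glance.sym_partition <- function(x, ...) {
  tibble(n_clones = x$n, ss_total = x$ss_total,
         n_permutations = x$design$n_permutations,
         seed = x$design$seed)
}

#' @rdname fit_partition
#' @param object A `sym_partition`.
#' @param ... Unused.
#' @export
autoplot.sym_partition <- function(object, ...) {
  tab <- filter(object$table, !.data$term %in% c("Residual", "Total"))
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot(tab, aes(x = .data$phi_ss, y = .data$term)) +
    geom_col(fill = "steelblue") +
    labs(x = "share of total SS", y = NULL) +
    theme_minimal()
}
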