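#' Count pairwise differences between two aligned sequences
#'
#' Simple (Hamming-style) difference count on the alignment. With
#' `gap_mode = "fifth_state"` the gap symbol `-` is a fifth character state:
#' gap vs base counts as a difference, gap vs gap as a match. With
#' `gap_mode = "ignore"` any column containing a gap in either sequence is
#' skipped.
#'
#' @param seq_a,seq_b Aligned sequences over `{A,C,G,T,-}`, equal length.
#' @param gap_mode `"fifth_state"` (default) or `"ignore"`.
#' @return Integer count of differing positions.
#' @export
pairwise_differences <- function(seq_a, seq_b,
                                 gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) {
    abort(sprintf("unequal aligned lengths (%d vs %d)", length(a), length(b)))
  }
  if (gap_mode == "ignore") {
    keep <- a != "-" & b != "-"
    a <- a[keep]
    b <- b[keep]
  }
  sum(a != b)
}

#' Variant-by-variant distance matrix
#'
#' @param variants Variant tibble; at least two rows.
#' @param gap_mode Gap handling, see [pairwise_differences()].
#' @return A `sym_dist` object: a symmetric numeric matrix with variant
#'   labels as dimnames and attributes `metric = "raw_differences"` and
#'   `gap_mode`.
#' @export
variant_distance_matrix <- function(variants,
                                    gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(variants) < 2) abort("need at least 2 variants")
  validate_variant_table(variants)
  chars <- do.call(rbind, strsplit(variants$sequence, ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(variants$label, variants$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[i, ]
      b <- chars[j, ]
      if (gap_mode == "ignore") {
        keep <- a != "-" & b != "-"
        a <- a[keep]
        b <- b[keep]
      }
      d[i, j] <- d[j, i] <- sum(a != b)
    }
  }
  new_sym_dist(d, metric = "raw_differences", gap_mode = gap_mode)
}

new_sym_dist <- function(m, metric, gap_mode = NULL) {
  structure(m, metric = metric, gap_mode = gap_mode,
            class = c("sym_dist", "matrix", "array"))
}

#' @export
print.sym_dist <- function(x, ...) {
  cat("<sym_dist> ", nrow(x), "x", ncol(x), " (", attr(x, "metric"), ")\n",
      sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Square-root transform a raw distance matrix
#'
#' Element-wise square root, applied once before matrices enter the
#' multifactor partition (mild down-weighting of the deep interclade
#' distances relative to within-clade ones).
#'
#' @param d A `sym_dist` with metric `"raw_differences"`.
#' @return A `sym_dist` with metric `"sqrt_differences"`.
#' @export
sqrt_transform <- function(d) {
  if (!identical(attr(d, "metric"), "raw_differences")) {
    abort("sqrt_transform expects a raw_differences matrix (already transformed?)")
  }
  new_sym_dist(sqrt(unclass(d)), metric = "sqrt_differences",
               gap_mode = attr(d, "gap_mode"))
}

#' Expand libraries to a clone-level distance matrix
#'
#' Each clone is one unit; the distance between two clones is the distance
#' between their variants. Returns the matrix together with the clone
#' factor table so that grouping statistics line up by position.
#'
#' @param libraries Screened, non-empty library tibble.
#' @param variant_dist A `sym_dist` over (at least) all variants present.
#' @return A list of class `sym_clone_dist` with elements `d` (clone x clone
#'   `sym_dist`) and `clones` (tibble: one row per clone with its variant
#'   and factors, in matrix order).
#' @export
clone_distance_matrix <- function(libraries, variant_dist) {
  if (nrow(libraries) == 0) abort("empty library set")
  miss <- setdiff(unique(libraries$variant), rownames(variant_dist))
  if (length(miss) > 0) {
    abort(paste0("variant absent from distance matrix: ",
                 paste(miss, collapse = ", ")))
  }
  clones <- tidyr::uncount(libraries, weights = .data$count)
  idx <- match(clones$variant, rownames(variant_dist))
  d <- unclass(variant_dist)[idx, idx, drop = FALSE]
  dimnames(d) <- list(clones$variant, clones$variant)
  structure(
    list(d = new_sym_dist(d, metric = attr(variant_dist, "metric"),
                          gap_mode = attr(variant_dist, "gap_mode")),
         clones = clones),
    class = "sym_clone_dist")
}

#' @export
print.sym_clone_dist <- function(x, ...) {
  cat("<sym_clone_dist> ", nrow(x$clones), " clones from ",
      dplyr::n_distinct(x$clones$sample_id), " libraries\n", sep = "")
  invisible(x)
}
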