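#' Statistical-parsimony connection limit
#'
#' Maximum number of mutational steps `j` for which a direct connection
#' between two haplotypes is considered parsimonious at the given
#' confidence. The probability of parsimony is estimated with a collision
#' model on the alignment: if `j` substitutions fall independently and
#' uniformly on `m` aligned positions, the chance that none are
#' superimposed (no position hit twice, hence no hidden homoplasy) is
#' \deqn{P(j; m) = \prod_{i=1}^{j-1} (1 - i/m),}
#' and the connection limit is the largest `j` with `P(j; m) >=` confidence.
#' `P` is 1 at `j <= 1`, strictly decreasing in `j`, increasing in `m`, and
#' the limit tends to `m` as the confidence tends to 0.
#'
#' @param aligned_length Number of aligned positions `m` (>= 1).
#' @param confidence Confidence level in (0, 1); 0.95 is the conventional
#'   choice for haplotype networks.
#' @return Integer connection limit (number of steps).
#' @examples
#' parsimony_limit(320)
#' @export
parsimony_limit <- function(aligned_length, confidence = 0.95) {
  stopifnot(aligned_length >= 1)
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)")
  }
  p <- parsimony_probability(seq_len(aligned_length), aligned_length)
  max(which(p >= confidence))
}

#' Probability of a parsimonious connection at j steps
#'
#' Vectorised helper behind [parsimony_limit()]; see that page for the
#' model.
#'
#' @param j Number of observed mutational steps (vectorised).
#' @param aligned_length Alignment length `m`.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
parsimony_probability <- function(j, aligned_length) {
  m <- aligned_length
  vapply(j, function(jj) {
    if (jj <= 1) return(1)
    i <- seq_len(jj - 1)
    i <- i[i < m]
    if (length(i) < jj - 1) return(0)
    prod(1 - i / m)
  }, numeric(1))
}

#' Build a statistical-parsimony haplotype network
#'
#' Deterministic TCS-style construction without inferred intermediate
#' haplotypes: candidate pairs are sorted by (steps, label order) and an
#' edge is added when its step count is at most the connection limit and it
#' joins two components at the minimum distance currently separating them.
#' Connected components are the subnetworks; pairs beyond the limit are
#' never joined directly, so deeply divergent clades fall into separate
#' subnetworks.
#'
#' @param variant_dist A raw-differences `sym_dist` over the screened
#'   variants.
#' @param counts Optional tibble of per-variant recovery counts with columns
#'   `variant`, `life_stage`, `count` (e.g. from screened libraries);
#'   attached to nodes as adult/egg tallies.
#' @param limit Connection limit in steps, e.g. from [parsimony_limit()].
#' @return A `sym_network`: list with `nodes` (tibble: label, subnetwork,
#'   total and per-life-stage counts), `edges` (tibble: from, to, steps),
#'   `limit`, and `graph` (an igraph object).
#' @export
build_network <- function(variant_dist, counts = NULL, limit) {
  labels <- rownames(variant_dist)
  if (is.null(labels) || length(labels) == 0) abort("empty variant set")
  d <- unclass(variant_dist)
  n <- length(labels)
  ord <- order(labels)

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  cand <- tibble(i = pairs[, 1], j = pairs[, 2],
                 steps = d[pairs]) |>
    filter(.data$steps <= limit) |>
    arrange(.data$steps, labels[.data$i], labels[.data$j])

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  # current minimum candidate distance between two components
  comp_min <- function(ci, cj) {
    mi <- which(vapply(seq_len(n), function(k) find(k) == ci, logical(1)))
    mj <- which(vapply(seq_len(n), function(k) find(k) == cj, logical(1)))
    min(d[mi, mj, drop = FALSE])
  }

  edges <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]; s <- cand$steps[r]
    ci <- find(i); cj <- find(j)
    if (ci == cj) {
      # within-component shortcut: keep edges at step 0/duplicated distance
      # only when they tie the existing minimum path? omitted: tree-like net
      next
    }
    if (s == comp_min(ci, cj)) {
      parent[cj] <- ci
      edges[[length(edges) + 1]] <-
        tibble(from = labels[i], to = labels[j], steps = s)
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(from = character(), to = character(), steps = numeric())

  comp <- vapply(seq_len(n), find, integer(1))
  subnet <- match(comp, unique(comp[order(labels)]))
  nodes <- tibble(label = labels, subnetwork = subnet)

  if (!is.null(counts)) {
    tall <- counts |>
      group_by(.data$variant, .data$life_stage) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "life_stage", values_from = "count",
                         values_fill = 0L, names_prefix = "n_")
    tall$n_total <- rowSums(tall[, -1, drop = FALSE])
    nodes <- left_join(nodes, tall, by = c(label = "variant"))
    nodes <- mutate(nodes, across(dplyr::starts_with("n_"),
                                  ~ dplyr::coalesce(.x, 0L)))
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, limit = limit, graph = g),
            class = "sym_network")
}

#' @export
print.sym_network <- function(x, ...) {
  cat("<sym_network> ", nrow(x$nodes), " haplotypes, ", nrow(x$edges),
      " edges, ", max(x$nodes$subnetwork), " subnetwork(s), limit ",
      x$limit, " steps\n", sep = "")
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes an edge-list TSV and a GraphML file carrying the node attributes
#' (subnetwork, per-life-stage counts).
#'
#' @param network A `sym_network`.
#' @param edge_path Output TSV path for the edge list.
#' @param graphml_path Optional output path for GraphML.
#' @return `edge_path`, invisibly.
#' @export
export_network <- function(network, edge_path, graphml_path = NULL) {
  readr::write_tsv(network$edges, edge_path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

#' @rdname build_network
#' @param object A `sym_network`.
#' @param ... Unused.
#' @export
autoplot.sym_network <- function(object, ...) {
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "label", "x", "y"), by = c(from = "label")) |>
    left_join(select(nodes, "label", "x", "y"), by = c(to = "label"),
              suffix = c("", "end"))
  size_col <- if ("n_total" %in% names(nodes)) nodes$n_total else 1
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = edges,
                 aes(xend = .data$xend, yend = .data$yend),
                 colour = "grey60") +
    geom_point(aes(size = size_col,
                   colour = factor(.data$subnetwork))) +
    geom_text(aes(label = .data$label), vjust = -1, size = 3) +
    scale_size_area(max_size = 10) +
    labs(colour = "subnetwork", size = "clones") +
    theme_minimal()
}
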