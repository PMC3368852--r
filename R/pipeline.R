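#' Run the full assemblage analysis end-to-end
#'
#' Orchestrates screening, distances, haplotype networks, per-colony
#' adult-vs-egg statistics, the nested multifactor partitions, the host
#' AMOVA and environmental summaries on one dataset bundle. Analyses whose
#' inputs are absent from the bundle are skipped with a notice in the
#' report. Deterministic given `seed`.
#'
#' @param bundle A [sym_bundle()].
#' @param n_perm Permutations for every permutation test (default 10000;
#'   999 is a fast setting).
#' @param seed Integer seed recorded in the report.
#' @param gap_mode Gap handling for distances (`"fifth_state"` default).
#' @param confidence Connection-limit confidence for the parsimony network.
#' @param phi Compute per-colony Phi permutation tests (distance-based;
#'   skip for count-only fixtures where sequences are placeholders)?
#' @param designs Optional list overriding [builtin_designs()].
#' @return A `sym_report` list: `screen`, `pair_table`, `network`,
#'   `partitions`, `host`, `env_summary`, `env_tests`, `notes`,
#'   `provenance`.
#' @export
run_all <- function(bundle, n_perm = 10000L, seed = 1L,
                    gap_mode = "fifth_state", confidence = 0.95,
                    phi = TRUE, designs = NULL) {
  findings <- validate_bundle(bundle)
  if (length(findings) > 0) {
    abort(paste0("bundle failed validation: ",
                 paste(findings, collapse = "; ")))
  }
  notes <- character()
  screen <- screen_variants(bundle$libraries, bundle$variants)
  libs <- apply_screen(bundle$libraries, screen)
  variants <- filter(bundle$variants,
                     .data$label %in% unique(libs$variant))

  vd <- variant_distance_matrix(variants, gap_mode)
  limit <- parsimony_limit(nchar(variants$sequence[1]), confidence)
  net_counts <- libs |>
    group_by(variant = .data$variant, life_stage = .data$life_stage) |>
    summarise(count = sum(.data$count), .groups = "drop")
  network <- build_network(vd, net_counts, limit)

  pair_table <- pair_stats(libs, variants, phi = phi, gap_mode = gap_mode,
                           n_perm = n_perm, seed = seed)

  partitions <- list()
  designs <- designs %||% builtin_designs(n_permutations = n_perm,
                                          seed = seed)
  main <- filter(libs, .data$morphology == "unknown")
  if (dplyr::n_distinct(main$site) >= 2 &&
      dplyr::n_distinct(main$year) >= 2) {
    cd <- clone_distance_matrix(main, sqrt_transform(vd))
    partitions$four_factor <- fit_partition(cd, designs$four_factor)
  } else {
    notes <- c(notes, "four-factor partition skipped: needs >=2 sites and >=2 years")
  }
  morph <- filter(libs, .data$morphology %in% c("branching", "plating"))
  if (dplyr::n_distinct(morph$morphology) == 2) {
    cd <- clone_distance_matrix(morph, sqrt_transform(vd))
    partitions$three_factor <- fit_partition(cd, designs$three_factor)
  } else {
    notes <- c(notes, "three-factor partition skipped: needs both morphologies at one site")
  }

  host <- NULL
  if (!is.null(bundle$genotypes)) {
    g <- bundle$genotypes
    host <- list(
      amova = hier_amova(g$individuals, allele_dist = g$allele_dist,
                         allele_seqs = g$allele_seqs,
                         n_perm = n_perm, seed = seed),
      exact = exact_test(genotype_allele_table(g$individuals),
                         chain_steps = max(n_perm, 10000L), seed = seed))
  } else {
    notes <- c(notes, "host analyses skipped: no genotypes in bundle")
  }

  env_summary <- NULL
  env_tests <- NULL
  if (!is.null(bundle$env)) {
    env_summary <- env_summarise(bundle$env)
    env_tests <- env_kruskal(bundle$env)
  } else {
    notes <- c(notes, "environment analyses skipped: no series in bundle")
  }

  structure(
    list(screen = screen, pair_table = pair_table, network = network,
         partitions = partitions, host = host,
         env_summary = env_summary, env_tests = env_tests, notes = notes,
         provenance = list(
           package_version = as.character(utils::packageVersion("symvert")),
           seed = as.integer(seed), n_perm = as.integer(n_perm),
           gap_mode = gap_mode, confidence = confidence,
           connection_limit = limit)),
    class = "sym_report")
}

# allele x group contingency table from a genotype table
genotype_allele_table <- function(individuals) {
  long <- tibble(
    allele = c(individuals$allele_a, individuals$allele_b),
    group = rep(individuals$group, 2))
  as.matrix(table(long$allele, long$group))
}

#' @export
print.sym_report <- function(x, ...) {
  cat("<sym_report>\n")
  cat("  screening: ", sum(x$screen$status == "retained"), " retained / ",
      sum(x$screen$status == "excluded"), " excluded\n", sep = "")
  cat("  colonies with adult+egg pair: ", nrow(x$pair_table), "\n", sep = "")
  cat("  network: ", max(x$network$nodes$subnetwork), " subnetwork(s), ",
      "limit ", x$network$limit, " steps\n", sep = "")
  cat("  partitions: ", paste(names(x$partitions), collapse = ", "), "\n",
      sep = "")
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' TSV per table plus one JSON bundle carrying provenance.
#'
#' @param report A `sym_report` from [run_all()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_screen(report$screen, file.path(dir, "screen.tsv"))
  readr::write_tsv(report$pair_table, file.path(dir, "pair_table.tsv"))
  export_network(report$network, file.path(dir, "network_edges.tsv"),
                 file.path(dir, "network.graphml"))
  for (nm in names(report$partitions)) {
    readr::write_tsv(tidy(report$partitions[[nm]]),
                     file.path(dir, paste0("partition_", nm, ".tsv")))
  }
  if (!is.null(report$host)) {
    readr::write_tsv(tidy(report$host$amova), file.path(dir, "host_amova.tsv"))
  }
  if (!is.null(report$env_summary)) {
    readr::write_tsv(report$env_summary, file.path(dir, "env_summary.tsv"))
    readr::write_tsv(report$env_tests, file.path(dir, "env_tests.tsv"))
  }
  jsonlite::write_json(
    c(report$provenance, list(notes = report$notes)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
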