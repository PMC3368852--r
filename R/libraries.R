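#' Read clone-library counts
#'
#' Reads a TSV of per-sample clone counts in either of two dialects,
#' auto-detected from the header:
#' \itemize{
#'   \item wide: one row per sample, first column `sample_id`, remaining
#'     columns named after variant labels, cells are non-negative integer
#'     counts (zero cells are dropped);
#'   \item long: columns `sample_id`, `variant`, `count`.
#' }
#'
#' @param path Path to the counts TSV.
#' @return A long tibble with columns `sample_id`, `variant`, `count`
#'   (all counts >= 1).
#' @export
read_clone_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("sample_id", "variant", "count") %in% names(x))) {
    counts <- x[, c("sample_id", "variant", "count")]
  } else {
    if (names(x)[1] != "sample_id") {
      abort("counts table must have 'sample_id' as first column (wide) or columns sample_id/variant/count (long)")
    }
    counts <- tidyr::pivot_longer(x, -"sample_id", names_to = "variant",
                                  values_to = "count")
    counts <- filter(counts, !is.na(.data$count), .data$count != 0)
  }
  validate_counts(counts)
}

validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    bad <- counts[counts$count < 0 | counts$count != round(counts$count), ]
    abort(paste0("negative or non-integer count for sample ",
                 paste(unique(bad$sample_id), collapse = ", ")))
  }
  counts$count <- as.integer(counts$count)
  counts <- filter(counts, .data$count > 0)
  tot <- summarise(group_by(counts, .data$sample_id), n = sum(.data$count))
  if (any(tot$n < 1)) abort("empty library")
  counts
}

#' Read sample metadata
#'
#' One row per sample with the factor columns used by the built-in designs:
#' `sample_id`, `colony_id`, `site`, `year`, `life_stage`, `morphology`.
#' Morphology may be `"unknown"`; it is never inferred from site.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble of sample metadata.
#' @export
read_metadata <- function(path) {
  need <- c("sample_id", "colony_id", "site", "year", "life_stage")
  x <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"morphology" %in% names(x)) x$morphology <- "unknown"
  x
}

#' Assemble clone counts and metadata into clone libraries
#'
#' @param counts Long counts tibble (see [read_clone_counts()]).
#' @param metadata Sample metadata tibble (see [read_metadata()]).
#' @return A tibble with one row per (sample, variant) carrying both the
#'   count and the sample's factors; the canonical library representation
#'   used throughout the package.
#' @export
build_libraries <- function(counts, metadata) {
  counts <- validate_counts(counts)
  orphan <- setdiff(unique(counts$sample_id), metadata$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("sample present in counts but absent in metadata: ",
                 paste(orphan, collapse = ", ")))
  }
  left_join(counts, metadata, by = "sample_id")
}

#' Bundle a dataset's components
#'
#' A bundle carries everything one analysis run needs: the variant table,
#' the clone libraries (long tibble with factors), and optionally a host
#' genotype table and environmental series.
#'
#' @param variants Variant tibble ([read_variants()]).
#' @param libraries Library tibble ([build_libraries()]).
#' @param genotypes Optional genotype list (see [hier_amova()]): a list with
#'   `individuals` (tibble: individual_id, allele_a, allele_b, group, sample)
#'   and `allele_dist` (named symmetric matrix) or `allele_seqs`
#'   (named character vector of aligned allele sequences).
#' @param env Optional environmental tibble with columns `site`, `variable`,
#'   `timestamp`, `value`.
#' @return An object of class `sym_bundle`.
#' @export
sym_bundle <- function(variants, libraries, genotypes = NULL, env = NULL) {
  structure(
    list(variants = variants, libraries = libraries,
         genotypes = genotypes, env = env),
    class = "sym_bundle")
}

#' @export
print.sym_bundle <- function(x, ...) {
  n_samp <- dplyr::n_distinct(x$libraries$sample_id)
  cat("<sym_bundle> ", nrow(x$variants), " variants, ", n_samp,
      " clone libraries (", sum(x$libraries$count), " clones)\n", sep = "")
  if (!is.null(x$genotypes)) {
    cat("  genotypes: ", nrow(x$genotypes$individuals), " individuals\n",
        sep = "")
  }
  if (!is.null(x$env)) {
    cat("  env: ", dplyr::n_distinct(x$env$site), " sites, ",
        dplyr::n_distinct(x$env$variable), " variables\n", sep = "")
  }
  invisible(x)
}

#' Cross-check a bundle for referential integrity
#'
#' Returns findings instead of erroring: the caller decides severity.
#'
#' @param bundle A [sym_bundle()].
#' @return A character vector of findings; empty when the bundle is
#'   fully consistent.
#' @export
validate_bundle <- function(bundle) {
  findings <- character()
  unknown <- setdiff(unique(bundle$libraries$variant), bundle$variants$label)
  if (length(unknown) > 0) {
    findings <- c(findings, paste0("unknown variant ", unknown))
  }
  if (any(bundle$libraries$count < 1)) {
    findings <- c(findings, "library with non-positive count")
  }
  need <- c("sample_id", "colony_id", "site", "year", "life_stage")
  miss <- setdiff(need, names(bundle$libraries))
  if (length(miss) > 0) {
    findings <- c(findings, paste0("libraries missing factor column ", miss))
  }
  if (!is.null(bundle$genotypes)) {
    g <- bundle$genotypes
    alleles <- unique(c(g$individuals$allele_a, g$individuals$allele_b))
    known <- if (!is.null(g$allele_dist)) rownames(g$allele_dist)
             else names(g$allele_seqs)
    bad <- setdiff(alleles, known)
    if (length(bad) > 0) {
      findings <- c(findings,
                    paste0("genotype allele without distance/sequence: ", bad))
    }
  }
  findings
}

#' Write a bundle's tabular components to a directory
#'
#' Writes `variants.fasta`, `flags.tsv`, `counts.tsv` (long dialect) and
#' `metadata.tsv` so that a bundle round-trips through [read_bundle()].
#'
#' @param bundle A [sym_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants(bundle$variants, file.path(dir, "variants.fasta"),
                 file.path(dir, "flags.tsv"))
  readr::write_tsv(bundle$libraries[, c("sample_id", "variant", "count")],
                   file.path(dir, "counts.tsv"))
  meta <- distinct(select(bundle$libraries, -"variant", -"count"))
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory holding `variants.fasta`, `flags.tsv`, `counts.tsv`,
#'   `metadata.tsv`.
#' @return A [sym_bundle()].
#' @export
read_bundle <- function(dir) {
  variants <- read_variants(file.path(dir, "variants.fasta"),
                            file.path(dir, "flags.tsv"))
  counts <- read_clone_counts(file.path(dir, "counts.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  sym_bundle(variants, build_libraries(counts, metadata))
}
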