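#' Read a table of named ITS2 sequence variants
#'
#' Parses an aligned FASTA of ITS2 variants plus an optional TSV sidecar of
#' per-variant flags into a validated variant table. Variant names follow the
#' field convention of clade letter + closest published type + decimal
#' (e.g. `C31`, `D1a.1`); the clade is taken from the leading letter unless a
#' `clade` column is supplied in the flags file.
#'
#' Sequences must arrive pre-aligned: all records are required to share one
#' aligned length, and `-` is the only recognised gap symbol. The package
#' never aligns sequences itself.
#'
#' @param fasta_path Path to an aligned FASTA file. Record ids are variant
#'   labels and must be unique.
#' @param flags_path Optional path to a TSV with columns `label` and any of
#'   `published`, `pseudogene`, `clade`. Labels absent from the file default
#'   to `published = FALSE`, `pseudogene = FALSE`.
#' @return A tibble with columns `label`, `clade`, `sequence`, `published`,
#'   `pseudogene` — one row per variant.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">C31", "ACGTACGT", ">C31.1", "ACGTACGA"), fa)
#' read_variants(fa)
#' @export
read_variants <- function(fasta_path, flags_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  labels <- names(seqs)
  labels <- sub("\\s.*$", "", labels)
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    abort(paste0("duplicate label in FASTA: ", paste(dup, collapse = ", ")))
  }
  variants <- tibble(
    label = labels,
    sequence = toupper(as.character(seqs))
  )
  flags <- NULL
  if (!is.null(flags_path)) {
    flags <- readr::read_tsv(flags_path, show_col_types = FALSE)
    if (!"label" %in% names(flags)) {
      abort("flags file must have a 'label' column")
    }
    extra <- setdiff(flags$label, variants$label)
    if (length(extra) > 0) {
      abort(paste0("flag labels not in FASTA: ", paste(extra, collapse = ", ")))
    }
  }
  as_variant_table(variants, flags = flags)
}

#' Build a validated variant table from label/sequence pairs
#'
#' @param x A data frame with at least `label` and `sequence` columns;
#'   optionally `clade`, `published`, `pseudogene`.
#' @param flags Optional data frame of flags keyed by `label` (columns among
#'   `published`, `pseudogene`, `clade`) merged over `x`.
#' @return A validated variant tibble (see [read_variants()]).
#' @export
as_variant_table <- function(x, flags = NULL) {
  x <- as_tibble(x)
  stopifnot(all(c("label", "sequence") %in% names(x)))
  if (!is.null(flags)) {
    flags <- as_tibble(flags)
    keep <- intersect(c("published", "pseudogene", "clade"), names(flags))
    x <- left_join(x, flags[, c("label", keep), drop = FALSE], by = "label",
                   suffix = c(".default", ""))
    x <- select(x, -dplyr::ends_with(".default"))
  }
  if (!"clade" %in% names(x)) x$clade <- NA_character_
  if (!"published" %in% names(x)) x$published <- NA
  if (!"pseudogene" %in% names(x)) x$pseudogene <- NA
  x <- mutate(
    x,
    clade = dplyr::coalesce(.data$clade, substr(.data$label, 1, 1)),
    published = dplyr::coalesce(as.logical(.data$published), FALSE),
    pseudogene = dplyr::coalesce(as.logical(.data$pseudogene), FALSE),
    sequence = toupper(.data$sequence)
  )
  validate_variant_table(x)
  x[, c("label", "clade", "sequence", "published", "pseudogene")]
}

validate_variant_table <- function(x) {
  if (anyDuplicated(x$label)) {
    abort(paste0("duplicate label: ",
                 paste(unique(x$label[duplicated(x$label)]), collapse = ", ")))
  }
  if (any(nchar(x$sequence) == 0)) {
    abort(paste0("empty sequence for: ",
                 paste(x$label[nchar(x$sequence) == 0], collapse = ", ")))
  }
  lens <- nchar(x$sequence)
  if (length(unique(lens)) > 1) {
    ref <- as.integer(names(which.max(table(lens))))
    bad <- x$label[lens != ref]
    abort(paste0("unequal aligned lengths; offending record(s): ",
                 paste(bad, collapse = ", ")))
  }
  bad_chr <- grepl("[^ACGT-]", x$sequence)
  if (any(bad_chr)) {
    abort(paste0("sequence contains symbols outside {A,C,G,T,-}: ",
                 paste(x$label[bad_chr], collapse = ", ")))
  }
  invisible(x)
}

#' Write a variant table to FASTA (and optional flags TSV)
#'
#' @param variants A variant tibble as returned by [read_variants()].
#' @param fasta_path Output FASTA path.
#' @param flags_path Optional output path for the flags TSV
#'   (`label`, `clade`, `published`, `pseudogene`).
#' @return `fasta_path`, invisibly.
#' @export
write_variants <- function(variants, fasta_path, flags_path = NULL) {
  ss <- Biostrings::BStringSet(variants$sequence)
  names(ss) <- variants$label
  Biostrings::writeXStringSet(ss, fasta_path, width = 80L)
  if (!is.null(flags_path)) {
    readr::write_tsv(
      variants[, c("label", "clade", "published", "pseudogene")], flags_path)
  }
  invisible(fasta_path)
}
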