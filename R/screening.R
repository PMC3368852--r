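#' Screen variants for inclusion in downstream statistics
#'
#' Applies the two inclusion rules used for ITS2 clone libraries before any
#' statistic is computed:
#' \enumerate{
#'   \item a variant is eligible if it was published previously, OR it was
#'     recovered at least `min_recoveries` times across libraries AND from at
#'     least `min_samples` distinct samples (clone singletons/doubletons from
#'     few samples are treated as likely PCR/cloning artefacts);
#'   \item a variant flagged as a putative pseudogene (aberrant ITS2
#'     secondary-structure fold, supplied as an input flag) is excluded
#'     regardless of publication status or abundance.
#' }
#' Adult and egg libraries from the same colony count as distinct samples.
#'
#' @param libraries Library tibble ([build_libraries()]).
#' @param variants Variant tibble ([read_variants()]).
#' @param min_recoveries,min_samples Recovery rule thresholds (defaults 3/3).
#' @return A `sym_screen` tibble with columns `label`, `status`
#'   (`"retained"`/`"excluded"`) and `reason` (`NA`, `"rare"` or
#'   `"pseudogene"`), one row per label observed in at least one library.
#' @examples
#' b <- table1_fixture()
#' screen <- screen_variants(b$libraries, b$variants)
#' table(screen$status)
#' @export
screen_variants <- function(libraries, variants,
                            min_recoveries = 3L, min_samples = 3L) {
  if (nrow(libraries) == 0) abort("no libraries to screen")
  tallies <- summarise(
    group_by(libraries, label = .data$variant),
    recoveries = sum(.data$count),
    samples = dplyr::n_distinct(.data$sample_id),
    .groups = "drop")
  tallies <- left_join(
    tallies, variants[, c("label", "published", "pseudogene")], by = "label")
  tallies <- mutate(
    tallies,
    published = dplyr::coalesce(.data$published, FALSE),
    pseudogene = dplyr::coalesce(.data$pseudogene, FALSE),
    eligible = .data$published |
      (.data$recoveries >= min_recoveries & .data$samples >= min_samples),
    status = dplyr::if_else(.data$eligible & !.data$pseudogene,
                            "retained", "excluded"),
    reason = dplyr::case_when(
      .data$status == "retained" ~ NA_character_,
      .data$pseudogene ~ "pseudogene",
      TRUE ~ "rare"))
  out <- arrange(select(tallies, "label", "status", "reason",
                        "recoveries", "samples"), .data$label)
  class(out) <- c("sym_screen", class(out))
  out
}

#' Restrict libraries to retained variants
#'
#' Drops clones of excluded variants from every library. A library whose
#' clones are all excluded survives as zero rows for that sample; downstream
#' statistics reject empty libraries explicitly.
#'
#' @param libraries Library tibble.
#' @param screen A `sym_screen` report from [screen_variants()].
#' @return The filtered library tibble.
#' @export
apply_screen <- function(libraries, screen) {
  keep <- screen$label[screen$status == "retained"]
  filter(libraries, .data$variant %in% keep)
}

#' Number of symbiont clades per library
#'
#' @param libraries Library tibble (typically screened).
#' @param variants Variant tibble supplying the `clade` of each label.
#' @return A tibble `sample_id`, `n_clades`.
#' @export
clade_count <- function(libraries, variants) {
  if (nrow(libraries) == 0) abort("empty library")
  x <- left_join(libraries, variants[, c("label", "clade")],
                 by = c(variant = "label"))
  summarise(group_by(x, .data$sample_id),
            n_clades = dplyr::n_distinct(.data$clade), .groups = "drop")
}

#' Write a screening report as TSV
#'
#' @param screen A `sym_screen` report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  readr::write_tsv(screen, path)
  invisible(path)
}
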