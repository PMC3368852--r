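# Printed clone-count fixture: 32 colony x year rows (adult + egg each),
# entered from the published per-sample retrieval superscripts. Sequences
# attached to the 29 labels are SYNTHETIC placeholders generated in code
# (family structure: satellites 1-3 substitutions from their dominant,
# clades C and D deeply divergent); statistics that depend only on counts
# (PSI, screening, clade tallies) are exact, distance-dependent statistics
# on this fixture are non-canonical.

table1_rows <- function() {
  # site, year, colony, adult counts, egg counts
  list(
    list("BTN", 2007, "1",  "C31:5,C31.2:2,C21:2,C17:1", "C32.2:8,C31:1"),
    list("BTN", 2007, "8",  "D1:4,D1a:4,D1a.1:2",
         "D1a:2,C31:2,C31.4:1,C21.2:1,C21.10:1,C17.2:1,C3:1"),
    list("BTN", 2007, "10", "D1a:4,D1:3,D1a.1:2", "C32.1:6,C31:2,C17.2:1"),
    list("BTN", 2007, "11", "D1a:7,D1:1,D1a.1:1", "D1a:5,D1a.1:3,D1:2"),
    list("BTN", 2007, "12", "D1:9,D1a:4",
         "C31:4,C17.2:2,D1a:1,C21:1,C31.1:1,C31.4:1,C32.1:1"),
    list("BTN", 2007, "18", "D1:3,D1a:3,D1a.1:2,D1a.2:1",
         "C31:9,C21:1,C17.2:1"),
    list("BTN", 2007, "19", "C31:3,C21:3,D1a:3,D1:1,D1a.1:1",
         "C31:5,C21.11:2,D1a:1,C17.2:1"),
    list("BTN", 2008, "8",  "D1:5,D1a:4",
         "C21:3,C31.1:2,D1a:1,C21.3:1,C21.8:1,C21.5:1"),
    list("BTN", 2008, "10", "D1:5,D1a:5,D1a.1:1",
         "D1:4,D1a.1:3,D1a:2,C21.11:1"),
    list("BTN", 2008, "19",
         "C21:2,C21.2:2,C21.1:1,C21.4:1,C21.7:1,C21.9:1,C21.11:1,C31:1",
         "C21:3,C21.5:1,C21.6:1,C21.8:1,C21.11:1,C17.1:1,C32.2:1,D1a:1"),
    list("GL", 2007, "23", "C17.2:5,C31:3,C17:1,C21.11:1,C3.1:1",
         "C17.2:3,C31:3,C17.1:1,C21:1,C32.2:1"),
    list("GL", 2007, "29", "C31:8,C21:1", "C31:5,C31.1:1,C31.2:1,C3.1:1"),
    list("GL", 2007, "30", "C21:4,C31:3,C17.2:2,C21.11:2",
         "C31:3,C17.2:3,C17:1,C21.3:1,C31.1:1,C31.3:1"),
    list("GL", 2007, "35", "D1a:6,D1:3,D1.3:1,D1a.1:1", "D1a:5,D1:4,D1.3:1"),
    list("GL", 2007, "36", "C31:5,C21:2,C17.1:1,C31.4:1,D1:1",
         "C31:7,C32.1:2,C31.1:1"),
    list("GL", 2007, "37", "C17.2:6,C21.1:2,C21:1,C21.10:1,C31.2:1",
         "C31:8,C17.2:1,C31.1:1"),
    list("GL", 2007, "39", "C31:6,C31.1:2,C17.1:1,C21:1,C31.3:1",
         "C31:6,C31.2:2,C31.1:1,C31.3:1,C3:1"),
    list("GL", 2008, "23", "C17.1:2,C31:2,C21:1,C21.4:1,C21.8:1",
         "C21:7,C17:1,C21.9:1,C31.2:1"),
    list("GL", 2008, "29", "C21:7,C31:2", "C21:9,C31:1"),
    list("GL", 2008, "37", "C21:5,C21.10:3,C21.2:1,C21.11:1,C31:1",
         "C31:3,C21:2,C21.8:2,C21.3:1,C21.5:1,C21.11:1"),
    list("PR", 2008, "B1", "C21:4,C21.6:2,C21.10:2,C21.11:2,C31.4:1",
         "C31:5,C21:2,C21.11:1,C3.1:1,D1:1,D1a.2:1"),
    list("PR", 2008, "B2", "C21:4,C31:4,C21.11:2,C17.2:1",
         "C17.2:4,C21:2,C21.4:1,C21.6:1,C21.7:1,C21.11:1,C31:1"),
    list("PR", 2008, "B5", "C21:3,C31:3,C21.7:2,C21.1:1,C21.11:1,C17.2:1",
         "C21:4,C31:3,C21.2:1,C21.11:1,C17.2:1,D1:1"),
    list("PR", 2008, "B6", "C21.9:3,C31:2,C21.4:2,C17.1:1,C21:1,C21.10:1",
         "C31:5,C17.2:3,C21.5:1,C17:1,C32.2:1"),
    list("PR", 2008, "B7", "C21:4,C31:3,C17.1:1,C17.2:1,C21.6:1,C21.11:1",
         "C31:3,C31.1:2,C31.2:2,D1.3:2,C21.11:1,C32.2:1"),
    list("PR", 2008, "B8", "C31:5,C21.8:2,C21:1,C21.1:1,C21.11:1,C31.1:1",
         "C21:6,C17.2:2,C31:2,C21.5:1,C21.9:1,C21.10:1"),
    list("PR", 2008, "P1", "C31:4,C21.1:2,C21.2:2,C17.1:1,C21:1,C21.11:1",
         "C21:4,C21.6:2,C31:2,C17.2:2,C21.5:1"),
    list("PR", 2008, "P2", "C31:3,C21:3,C21.11:3,C17.2:1,C21.4:1",
         "C31:3,C21:3,C17.2:1,C21.6:1,D1a:1"),
    list("PR", 2008, "P5",
         "C31:5,C3:1,C21:1,C21.7:1,C21.10:1,C21.11:1,C31.2:1",
         "D1a.1:5,D1:4,D1a:3,D1a.2:1"),
    list("PR", 2008, "P6", "C31:3,C21:3,C21.3:2,C21.11:2,C21.2:1",
         "C21:5,C31:3,C21.4:1,C21.11:1,C3:1"),
    list("PR", 2008, "P7", "D1a.1:7,D1a:3,C21:1,C21.8:1",
         "D1a:4,D1a.1:1,D1:1,C21:1,C21.8:1"),
    list("PR", 2008, "P9", "C21:6,C21.5:1,C21.8:1,C31:1,C17.2:1",
         "C21:4,C21.11:2,C21.2:1,C21.3:1,C21.8:1,C31:1,D1a.1:1"))
}

parse_counts <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble(variant = vapply(kv, `[`, "", 1),
         count = as.integer(vapply(kv, `[`, "", 2)))
}

# labels previously published in independent studies
table1_published <- c("C3", "C17", "C21", "C21.6", "C21.11", "C31",
                      "C31.1", "D1", "D1a")
# labels flagged as pseudogenes by aberrant secondary-structure folding
table1_pseudogenes <- c("C32.1", "C32.2")

# family structure used to synthesise placeholder sequences: each satellite
# sits 1-3 substitutions from its dominant; C32.x branch from C21.11
table1_families <- function() {
  list(
    C3 = "C3.1",
    C17 = c("C17.1", "C17.2"),
    C21 = paste0("C21.", 1:11),
    C31 = paste0("C31.", 1:4),
    C21.11 = c("C32.1", "C32.2"),
    D1 = "D1.3",
    D1a = c("D1a.1", "D1a.2"))
}

table1_sequences <- function(aligned_length = 320L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(38440L)
  m <- aligned_length
  seqs <- list(C3 = random_seq(m))
  seqs$D1 <- mutate_seq(seqs$C3, round(0.25 * m))$sequence
  # remaining dominants a handful of substitutions from their clade base
  seqs$C17 <- mutate_seq(seqs$C3, 4)$sequence
  seqs$C21 <- mutate_seq(seqs$C3, 5)$sequence
  seqs$C31 <- mutate_seq(seqs$C3, 3)$sequence
  seqs$D1a <- mutate_seq(seqs$D1, 3)$sequence
  fams <- table1_families()
  for (dom in names(fams)) {
    for (i in seq_along(fams[[dom]])) {
      lab <- fams[[dom]][i]
      if (is.null(seqs[[lab]])) {
        k <- ((i - 1) %% 3) + 1
        seqs[[lab]] <- mutate_seq(seqs[[dom]], k)$sequence
      }
    }
  }
  seqs
}

#' Published clone-count fixture
#'
#' The full 32-colony x year clone-count table (64 libraries: one adult
#' and one egg library per colony x year) with per-variant retrieval
#' counts exactly as printed, sample metadata (site, year, life stage,
#' colony, morphology) and the published/pseudogene flags for the 29
#' observed ITS2 variants. Sequences are synthetic placeholders built in
#' code (see the package vignette); count-based statistics on this fixture
#' are exact, distance-based ones are illustrative only.
#'
#' @param aligned_length Length of the synthetic placeholder sequences.
#' @return A [sym_bundle()].
#' @examples
#' b <- table1_fixture()
#' validate_bundle(b)
#' @export
table1_fixture <- function(aligned_length = 320L) {
  rows <- table1_rows()
  libs <- bind_rows(lapply(rows, function(r) {
    meta <- tibble(
      site = r[[1]], year = r[[2]], colony_id = paste0(r[[1]], "_", r[[3]]),
      morphology = dplyr::case_when(
        r[[1]] == "PR" & startsWith(r[[3]], "B") ~ "branching",
        r[[1]] == "PR" & startsWith(r[[3]], "P") ~ "plating",
        TRUE ~ "unknown"))
    bind_rows(
      mutate(parse_counts(r[[4]]), life_stage = "adult"),
      mutate(parse_counts(r[[5]]), life_stage = "egg")) |>
      dplyr::cross_join(meta) |>
      mutate(sample_id = paste(.data$colony_id, .data$year,
                               .data$life_stage, sep = "_"))
  }))
  seqs <- table1_sequences(aligned_length)
  labels <- sort(unique(libs$variant))
  variants <- as_variant_table(tibble(
    label = labels,
    sequence = unlist(seqs[labels]),
    published = labels %in% table1_published,
    pseudogene = labels %in% table1_pseudogenes))
  sym_bundle(variants,
             libs[, c("sample_id", "variant", "count", "colony_id", "site",
                      "year", "life_stage", "morphology")])
}
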