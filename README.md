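# symvert

Analysis of symbiont ITS2 sequence assemblages in vertically transmitting
corals: given clone-library counts of ITS2 variants from parent colonies and
the eggs they release, `symvert` quantifies how faithfully the parental
symbiont (Symbiodiniaceae) community is passed to the next generation, and
how parental assemblages are structured by site, year, life stage, colony
and morphology.

It is written for coral/symbiont molecular ecologists working with
clone-library (or analogously sparse amplicon) data: samples-by-variant
count tables, aligned variant sequences, diploid host genotypes and
site-level environmental loggers.

## What it computes

* **Clone-library screening** — a variant enters the statistics only if it
  was published previously or recovered ≥ 3 times from ≥ 3 independent
  samples; variants flagged as putative pseudogenes (aberrant ITS2
  secondary-structure folds) are excluded regardless.
* **Genetic distances** — simple pairwise differences on the alignment
  (Hamming), with gaps either a fifth character state or ignored;
  element-wise square-root transform for the multivariate partition.
* **Statistical-parsimony haplotype networks** — TCS-style networks per
  dataset with a confidence-based connection limit; deeply divergent clades
  (C vs D) fall into separate subnetworks.
* **Percent similarity index (Renkonen/Wolda)** per colony between adult
  and egg libraries: `PSI = Σ_v min(p_v, q_v)` on relative abundances;
  0 = no shared variants, 1 = identical composition.
* **Two-group distance AMOVA** per colony:
  `Φ = σ²_among / (σ²_among + σ²_within)` from squared inter-clone
  distances, with a clone-permutation p-value (add-one rule).
* **Nested multifactor distance partitioning** (PERMANOVA-style, Gower
  centering + sequential projections) for the published four-factor
  (site / year / life stage / colony-in-site) and three-factor
  (morphology / life stage / colony-in-morphology) designs, pseudo-F and
  permutation p per term.
* **Hierarchical diploid AMOVA** on host nuclear-intron genotypes
  (groups > samples > individuals > allele copies) with Φ statistics per
  level, plus an exact test of population non-differentiation (complete
  enumeration for small tables, a fixed-margin Markov chain otherwise).
* **Environmental summaries** and Kruskal–Wallis site comparisons.
* **A synthetic-data generator** producing complete bundles with the same
  structure (7–13 clones/sample, satellites 1–3 bp from dominants, two
  divergent clades, site-dependent composition, faithful or shifted egg
  transmission) so every stage is testable without external data.

## Worked example

The package ships the printed clone-count table of the study system as a
programmatic fixture (64 libraries, 659 clones; sequences are synthetic
placeholders, so count-based statistics are exact and distance-based ones
illustrative):

```r
library(symvert)
library(dplyr)

b <- table1_fixture()
b
#> <sym_bundle> 29 variants, 64 clone libraries (659 clones)

screen <- screen_variants(b$libraries, b$variants)
filter(screen, status == "excluded")
#> # A tibble: 2 × 5
#>   label status   reason     recoveries samples
#>   <chr> <chr>    <chr>           <int>   <int>
#> 1 C32.1 excluded pseudogene          9       3
#> 2 C32.2 excluded pseudogene         12       5

libs <- apply_screen(b$libraries, screen)
pair_stats(libs, b$variants) |> head(5)
#> # A tibble: 5 × 6
#>   site   year colony_id s_adult s_egg   psi
#>   <chr> <dbl> <chr>       <int> <int> <dbl>
#> 1 BTN    2007 BTN_1           1     1 0.5
#> 2 BTN    2007 BTN_8           1     2 0.222
#> 3 BTN    2007 BTN_10          1     1 0
#> 4 BTN    2007 BTN_11          1     1 0.722
#> 5 BTN    2007 BTN_12          1     2 0.1
```

Colony 1's egg library is dominated by the pseudogene-flagged C32.2; after
screening only C31 remains, shared with half of the adult library, hence
PSI = 0.50. Colony 10's adult hosts only clade D while its screened egg
library holds only clade C variants — PSI = 0 (no overlap). `s_adult`/
`s_egg` count symbiont clades per library.

The whole pipeline in one call:

```r
rep <- run_all(b, n_perm = 199, seed = 1, phi = FALSE)
rep
#> <sym_report>
#>   screening: 27 retained / 2 excluded
#>   colonies with adult+egg pair: 32
#>   network: 2 subnetwork(s), limit 6 steps
#>   partitions: four_factor, three_factor
#>   note: host analyses skipped: no genotypes in bundle
#>   note: environment analyses skipped: no series in bundle
```

The 27 retained variants form two parsimony subnetworks — one per clade —
because the C–D divergence far exceeds the 6-step connection limit for a
320-position alignment at 95% confidence. `tidy(rep$partitions$four_factor)`
gives the per-term partition table; `write_report(rep, "out/")` writes
every table as TSV plus a provenance JSON; `autoplot(rep$network)` draws
the haplotype network.

`phi = TRUE` (the default) adds per-colony Φ and permutation p-values,
which require real (not placeholder) aligned sequences to be meaningful.

## Scope notes

The package consumes pre-aligned sequences and precomputed pseudogene
flags; it does not align, BLAST, fold RNA structures, or phase genotypes.
See the methods vignette (`vignettes/assemblage-methods.Rmd`) for the
statistical models, parameter defaults and known limitations.
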