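---
title: "Methods: symbiont assemblage statistics in symvert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbiont assemblage statistics in symvert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symvert)
```

`symvert` analyses multisets of ITS2 sequence variants ("sequence
assemblages") recovered from clone libraries of coral tissue and eggs. ITS2
is a multicopy marker: intra-genomic variants make "type" counting
unreliable, so the unit of analysis throughout is the assemblage — the
vector of per-variant recovery counts in one sample — never an inferred
species count. This vignette documents the models, the defaults and why
they are set where they are, the numerical conventions, and what the
synthetic generator does and does not emulate.

## Screening

A variant is retained iff it is *published* (verified in independent
studies), or recovered at least 3 times across libraries **and** from at
least 3 distinct samples; a pseudogene flag (aberrant secondary-structure
fold, supplied as input — `symvert` does not fold RNA) excludes a variant
unconditionally, even if published or abundant. Two interpretation choices
are deliberate and visible in the API:

* **"Independent samples" means distinct `sample_id`s.** The adult and egg
  libraries of one colony are two samples. The recovery rule is a guard
  against PCR/cloning artefacts, which arise per amplification — and adult
  and egg tissue were amplified separately.
* **Screening happens once, dataset-wide, before every statistic,**
  including the per-colony similarity index. The printed per-colony values
  of the study system are only reproducible this way (e.g. a colony whose
  egg library is dominated by a pseudogene-flagged variant).

Screening is idempotent and monotone: re-applying a report changes
nothing, and adding recoveries can only move a variant towards retention.

## Distances

"Simple pairwise genetic distance" is realised as Hamming differences on
the supplied alignment — the conventional default for distance AMOVA on
haplotypes, and the only choice that needs no substitution model. Gaps are
a **fifth character state** by default (gap vs base differs, gap vs gap
matches), matching the convention used for statistical-parsimony networks;
`gap_mode = "ignore"` drops gapped columns instead, and every
fifth-state distance is ≥ its gap-ignoring counterpart. Alignment is an
input: the package never aligns.

The multifactor partition receives **square-root-transformed** distances.
The transform compresses the deep interclade distances (two clades ~25%
divergent) relative to the 1–3-step within-clade distances, so the
partition is not driven entirely by clade identity; per-colony two-group
AMOVA uses raw differences (squared inside the sums of squares), keeping
the two analyses as published.

## Statistical-parsimony networks

Variants are joined in order of increasing step distance; an edge is added
when it joins two components at the minimum distance currently separating
them and that distance does not exceed the **connection limit**. Ties are
broken lexicographically by label, so construction is deterministic.
Unsampled intermediate haplotypes are not materialised: the quantity
interpreted downstream is the partition into subnetworks, which the
simplified construction preserves (components are exactly the connected
components of the ≤-limit graph, so lowering the limit can only split,
never merge).

The connection limit is the largest step count `j` whose probability of
parsimony is at least the confidence (default 0.95). We estimate that
probability with a collision model: if `j` substitutions land independently
and uniformly on `m` aligned positions, the chance that none are
superimposed (hence no hidden multiple hits) is

$$P(j; m) = \prod_{i=1}^{j-1}\left(1 - \frac{i}{m}\right).$$

This estimator is exact under its stated model, strictly decreasing in
`j`, increasing in `m`, and tends to admit everything as the confidence
tends to 0. For `m = 320` at 0.95 it gives a 6-step limit. It is simpler
than the classical coalescent-based recursion used by the original TCS
software and will generally be somewhat more conservative; since the
analyses here interpret only the component structure (clades separate,
families connect), and the interclade distance (~80 steps at default
divergence) dwarfs any reasonable limit, the conclusions are insensitive
to the estimator choice.

## Per-colony statistics

**PSI** (Renkonen/Wolda percent similarity) between adult and egg:
`Σ_v min(p_v, q_v)` over relative abundances. It is reported as a
proportion with two decimals; the printed table rounds halves away from
zero (0.625 prints as 0.63) and the tests follow that convention. PSI is
symmetric and invariant to rescaling either library's counts.

**Two-group AMOVA** uses the distance formulation: with squared clone
distances, `SS_total = (1/N) Σ_{i<j} d²`, within-group SS analogously per
group, and variance components from the standard expectations with
`n₀ = (N − Σ n_g²/N)/(k−1)`. Φ is among-variance over total. Negative Φ
estimates are reported as-is — they are the usual finite-sample behaviour
of components-of-variance estimators, and truncating them would bias
permutation calibration. If both components are zero (all clones
identical) Φ is defined as 0. The permutation test exchanges clones
between the two libraries, preserving sizes, and uses the add-one rule
`p = (1 + #{Φ* ≥ Φ}) / (1 + n_perm)`, so p is never 0 and `p < 0.001`
is attainable from 999 permutations up.

## Multifactor partition

The McArdle–Anderson machinery: Gower-centred inner-product matrix
`G = −½ J D² J`, sequential (Type I) projections onto the model terms in
the published order, `SS_term = tr((H_k − H_{k−1}) G)`, pseudo-F against
the residual mean square, permutation p per term. Choices worth knowing:

* **Sequential SS in the published term order** handles the unbalanced
  layouts (sites sampled in different years, morphology only at one site)
  predictably; SS are additive to the total by construction and the tests
  assert it to 1e−8.
* **Denominators.** The original mixed-model software chose
  expected-mean-square denominators that are not recoverable from the
  published text, so the residual MS is the default denominator and the
  printed per-term MS/Φ/p of the study are *not* reproduction targets; a
  per-term `denominators` override exists for experimentation.
* **Permutation strategy.** Unrestricted permutation of clones is the
  default and is exact only when clones are exchangeable under the null of
  the tested term. With library- or colony-level heterogeneity it is an
  approximation; `permute = "library"` exchanges whole libraries instead.
  The calibration tests therefore use a generator regime with a single
  shared composition (no colony heterogeneity, very large
  Dirichlet concentration), where clone exchangeability holds and null
  p-values are uniform (KS distance < 0.1 over 500 simulations).
* A term whose design columns add no rank (confounded with earlier terms)
  raises an error naming the term rather than silently reporting 0 df.
* The report includes both the pseudo-F and an SS-ratio effect size
  (`phi_ss = SS_term/SS_total`), clearly labelled, because the published
  tables print a per-term "Φ" whose exact mapping onto the
  pseudo-F machinery is not stated.

## Host diploid AMOVA and exact test

Four levels — groups > samples > individuals > allele copies — with the
two-level grouping hierarchy supplied explicitly (the published sample
layer within morphology/site is not defined precisely enough to infer).
Each individual contributes exactly two allele copies, so the
among-individual coefficient is exactly 2; the among-sample and
among-group coefficients use the standard unbalanced-size formulas. Φ per
level are the usual cumulative ratios; negative components are reported
as-is; percentages sum to 100 by construction. A degenerate dataset (all
copies identical) is flagged and all Φ set to 0. Permutations per level
exchange the level-appropriate units: samples among groups, individuals
among samples within groups, allele copies among individuals (within
samples, and globally for the within-individual statistic).

The exact test of non-differentiation conditions on the margins of the
allele × population count table. Totals up to 12 are handled by complete
enumeration of fixed-margin tables (p = summed conditional probability of
all tables no more probable than the observed, cross-checked against
`fisher.test`); larger tables use a Metropolis chain over fixed-margin
tables with 2×2 ±1 switch proposals, whose estimate agrees with the
enumeration within 0.02 at 10⁵ steps on the enumerable tables. The chain
p-value also uses an add-one rule so it is never exactly 0.

## Environmental statistics

Site summaries are arithmetic mean, n−1 SD and range. The Kruskal–Wallis
test applies the tie correction (wrapped from `stats::kruskal.test`):
logger series recorded at 0.2 °C resolution tie heavily, and the
uncorrected statistic would be systematically deflated. All-identical
input is answered with H = 0, p = 1 rather than an error. The published H
values require the raw logger series, which are not printed, so the tests
assert the rank-test invariances (identical groups, monotone transforms)
instead.

## The synthetic generator

`simulate_bundle()` emulates the features the statistics rely on:

* two clades diverged at 25% of positions (a stand-in; no empirical figure
  exists for the ancestors), dominants a few substitutions apart,
  satellites exactly 1–3 substitutions from a recorded dominant with every
  edit logged for oracle checks;
* clone libraries of 7–13 clones (as observed), drawn
  Dirichlet-multinomially around a per-colony composition
  (`overdispersion`, default 15) which is itself drawn around a site
  profile (`colony_heterogeneity`, default 8); the first main site is
  clade-D-rich (default 0.8) and the others clade-C-rich, mirroring the
  observed site contrast;
* egg models: `faithful` (egg composition equals the parent's) and
  `shifted` (clade-D-dominated parents transmit eggs mixed towards a
  clade-C profile, default weight 0.6), the pattern observed in the study
  system;
* optional pseudogene-flagged satellites, a morphology site with both
  colony forms, and complete metadata for both built-in designs.

It does **not** emulate PCR/cloning bias, chimeras, within-colony spatial
structure, or a temporal model linking years (year-to-year change is
redrawn, not evolved). Passing tests on synthetic data therefore show the
statistics behave correctly under the stated sampling model — not that the
model captures every feature of real clone libraries.

The Dirichlet-multinomial is the natural minimal overdispersion model for
clone counts (a small sample of an underlying community); no sampling
model is stated in the source material. Identical seeds reproduce bundles
byte-for-byte.

## Problem sizes in the test suite

The suite pins every estimator to an independent brute-force oracle on
small inputs (two-group AMOVA: 200 random libraries of ≤ 10 clones at
1e−10; host AMOVA: 12-individual tables at 1e−10; enumeration vs chain on
total-≤12 tables), calibrates the permutation tests by simulation (1000
null two-group datasets; 100 seeds for site-effect recovery; 500 null fits
for p-value uniformity), and asserts the printed 32-colony PSI column
exactly at two decimals. These sizes keep the full suite under a few
minutes on one CPU while leaving the Monte-Carlo bands comfortably wide of
their thresholds.

## Known limitations

* The parsimony-probability estimator is a documented simplification (see
  above); absolute connection limits from other software will differ by a
  few steps.
* Unrestricted clone permutation is approximate for terms above the
  library level; use `permute = "library"` for colony-level terms.
* Distance-based statistics on the printed-count fixture use synthetic
  placeholder sequences and are illustrative only; PSI, screening and
  clade counts on that fixture are exact.
* The multifactor partition reports Type I SS: term order matters in
  unbalanced layouts, and the built-in designs fix the published order.
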