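---
title: "Y-STR haplotype analysis for surname studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype analysis for surname studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrtools)
```

## The setting

Y-chromosome short tandem repeats (Y-STRs) lie on the non-recombining,
male-specific part of the Y chromosome. A male's alleles across a panel of
Y-STR loci — his haplotype — is inherited from his father as a single
block, so, barring mutation, all males of one paternal line carry the same
haplotype. Surnames in many cultures are inherited the same way, which is
why surname studies compare Y-STR haplotypes: a surname group descended
from one founder should show a cluster of identical or near-identical
haplotypes, while unrelated lines differ at most loci.

`ystrtools` works on the 16-locus Yfiler panel (`ystr_panel()`), with the
European minimal haplotype and the SWGDAM set available as sub-panels. One
locus, DYS385, is duplicated and typed as an unordered pair of alleles;
single-copy loci can also show duplicated two-allele patterns in some
males, and the data model keeps such patterns intact rather than collapsing
them to one allele. Alleles are numeric repeat counts; microvariants
(e.g. 13.2) are supported. Missing data is handled only by explicit
masking: every stored haplotype covers the full panel, and analyses that
should skip a locus say so (`mask =`, `ignore =`).

## The locus-match rule

Every analysis rests on one binary comparison, `locus_match()`: two allele
sets match if and only if they are equal as multisets. Both alleles of a
DYS385 pair must agree, and a duplicated pattern such as {15,16} does not
match the single allele {15}. No partial credit and no mutation-step
weighting is applied anywhere; distances that weight by repeat-count
difference are deliberately out of scope.

This exact-multiset rule is validated against the study's published
pairwise table: of the candidate rules (exact multiset, any-shared-allele,
Jaccard), only exact multiset reproduces all nine printed adjacent-pair
percentages, in particular the OB8–OB9 cell, where sample OB9's duplicated
DYS437 pattern would otherwise count as a match.

## Pairwise similarity and identity classes

`percent_similarity()` reports `100 · matched/compared` over a panel,
rounded half-up to two decimals. On the full 16-locus panel every reachable
value is an exact multiple of 6.25, so rounding never alters a result; the
rounding convention only matters for masked or partial panels, where the
denominator is the number of loci actually compared (a masked locus is not
a mismatch). `similarity_matrix()` stores the full symmetric matrix and
prints the lower triangle, the layout of published pairwise tables.
`identity_classes()` partitions a population by complete-haplotype
identity; a pair lands in one class exactly when its similarity is 100.

## Frequencies and signatures

`haplotype_frequency()` is the ISFG counting method ("frequentist
approach"): X/N, the number of database haplotypes identical to the query
over the database size. We report plain X/N with no confidence interval
and no (X+1)/(N+1)-style augmentation, matching the procedure the fixtures
were analysed with; `format_one_in_n()` renders the familiar "1 in n"
form, with an explicit "not observed" marker at zero rather than a
division.

`allele_frequency()` has two counting modes, and the distinction matters
whenever a sample carries two alleles at a locus. Exact mode treats the
whole allele set as the unit — {15,16} is its own key, and percentages sum
to 100. Carrier mode counts a sample towards every allele it carries.
`footprint_sharing()` uses exact mode, locus by locus, against a founder
signature. On the packaged surname fixture this reproduces 13 of the 14
published per-locus sharing percentages, including the discriminating
DYS437 value (70%: the duplicated {15,16} sample does not count as a
15-carrier). The one exception is DYS385, published as 80%: the exact pair
{11,14} occurs in 40% of the samples, while 80% is the carrier frequency
of allele 11 alone. No single rule yields the published list at all 14
loci, so the package reports the exact-mode value and documents the
discrepancy rather than special-casing one locus.

Founder signatures are partial haplotypes. The shipped Dal Riata signature
stores DYS389II = 16 exactly as published, although haplotype tables report
28–33 at that locus (16 is consistent with the DYS389b convention, i.e.
DYS389II minus DYS389I); since every published classification excepts
DYS389II, `classify_population()` defaults are used with
`ignore = "DYS389II"` and the discrepancy stays quarantined in the stored
signature. Classification is strict: every non-ignored signature locus must
match exactly; an empty signature matches vacuously.

The control-group sharing comparison published alongside the surname list
used an unidentified 10-member subset of the 22 control samples; it is not
reproducible as printed, so no test or report depends on it — operations
that need such a subset take it as an explicit argument.

## The simulator

`simulate_lineage()` embodies the inheritance model the analyses assume: a
founder haplotype transmitted through `generations` meioses, each allele
copy mutating per meiosis with its locus rate, a mutation moving the
repeat count by ±1 with equal probability (single-step symmetric stepwise
mutation model), floored at one repeat. Simplifications, stated as such:
no multi-step mutations, no upper length bound, and a *star genealogy* —
each descendant is an independent chain from the founder rather than a
branching pedigree. That is sufficient to produce the within- versus
between-cluster similarity gradients surname studies interpret; a shared
pedigree would only correlate descendants and is out of scope, as are
coalescent machinery, population growth and SNP/haplogroup simulation.

The default rate, 0.002 per locus per meiosis, is the order of magnitude
typical of Y-STR loci; it is configurable per locus
(`mutation_model(rate, per_locus = ...)`). With rate 0 the simulator
reproduces identity by descent exactly, which ties it to the frequency
module: the founder's counting-method frequency in its own mutation-free
cluster is 1.

`simulate_unrelated()` draws each locus independently from per-locus allele
frequency tables (two independent draws for DYS385, one elsewhere), e.g.
tables derived from a population with `allele_tables()`, which counts
allele copies — including both copies of duplicated patterns — and
normalizes. It emulates a control group with no paternal structure; it does
not model linkage between loci (real haplotypes are a single linked block,
so simulated unrelated samples are *more* independent across loci than real
ones) and never generates duplicated patterns at single-copy loci.
`simulate_surname_study()` combines founder clusters and an unrelated group
under one seed; identical designs and seeds give byte-identical serialized
output, and seeded calls restore the caller's RNG state.

What passing simulator-based tests shows, and what it does not: the
analysis pipeline behaves correctly on data with the statistical structure
the model assumes (clusters of near-identical haplotypes against a
dissimilar background). Real data add features the generator omits —
population-shared haplotype frequencies, mutation rate heterogeneity
beyond the per-locus table, multi-step mutations, typing artefacts — so
simulator checks validate the software, not the population-genetic
inferences drawn from any particular study.

## Numerical and design choices

- **Rounding**: half-up to 2 decimals for percent similarity (`round()`
  rounds half to even, which would be surprising in printed-table
  comparisons); "1 in n" uses half-up to an integer.
- **Modal-allele ties**: broken towards the smallest allele value —
  arbitrary but deterministic; the fixtures contain no ties at the loci
  whose modal alleles are reported.
- **Allele storage**: numeric, with 13 ≡ 13.0; serialization writes
  integers without a decimal part and preserves microvariant parts.
- **CSV dialect**: semicolon separates alleles within a cell so unquoted
  CSV stays parseable; the printed-table comma convention ("11,14") is
  accepted on input inside quoted cells. Header tokens are
  case-insensitive; "YGATAH" and "Y GATA H4" are accepted aliases of
  YGATAH4; unknown extra columns are preserved as free-text metadata
  (county names and the like are not validated against a gazetteer).
- **Degenerate inputs**: empty populations are valid for I/O and
  classification (zero matches) but rejected where a denominator is needed
  (frequencies, similarity matrices); empty allele sets and empty
  comparison panels are errors, never silent zeros.
- **Problem sizes in the test suite**: the stochastic simulator checks use
  2 000 descendants over 10 generations for the closed-form identity
  bound (3 Monte-Carlo standard errors), 5 000 unrelated draws for the
  binomial sampling check, two 15-member clusters for the within/between
  contrast, and 100 replicates for the depth-monotonicity property —
  sizes at which the Monte-Carlo error is far below the effects being
  asserted while the suite stays quick to run.

## Known limitations

- The footprint-sharing DYS385 figure cannot reconcile exact and carrier
  counting (see above); users comparing against published lists should
  check which rule a source used.
- The counting method is reported without sampling uncertainty; for
  forensic weight-of-evidence, likelihood-ratio or Bayesian approaches on
  large reference databases are the appropriate tools and are not
  implemented here.
- The simulator's star genealogy understates haplotype correlation within
  deep real pedigrees, and `simulate_unrelated()` ignores inter-locus
  linkage.
- External database lookups (the "1 in n" figures quoted from national
  Y-STR databases) depend on those databases' compositions and are out of
  scope; only the formatting of such estimates is provided.
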