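---
title: "Mining co-prescription patterns in herbal formulae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining co-prescription patterns in herbal formulae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbminer)
```

`herbminer` analyzes collections of multi-herb prescriptions. This
vignette is the package's account of the underlying methods: the data
model, each stage's statistic and its assumptions, the tunable parameters
and their defaults, the synthetic generators used for validation, and the
design decisions taken where more than one reasonable convention exists.

## The transaction model

The unit of analysis is the **prescription**, not the patient: a patient
seen repeatedly contributes one transaction per visit. This matches how
relative frequencies are read clinically (a herb prescribed in 231 of 299
prescriptions has frequency 77.3 % *of prescriptions*), and it means
repeated visits by the same patient are treated as exchangeable
transactions — a deliberate simplification that ignores within-patient
correlation. Patient identifiers are carried as metadata but never used.

Standardization maps every raw herb string to a canonical name through an
explicit alias index (canonical names, pinyin, spelling variants), after
trimming whitespace and case-folding. Matching is otherwise **exact**:
romanization variants must be registered as aliases, and unknown strings
raise an error (or are logged and skipped under `on_unknown = "skip"`).
Fuzzy matching is deliberately absent — a silent approximate match
corrupts every downstream count, whereas a hard error is visible and
fixable. How the original clinical workflow handled unmappable strings is
generally not documented in published analyses; strict-by-default with an
explicit skip log is this package's answer. Registered compound formulae
are decomposed into their constituent herbs before de-duplication, so a
prescription becomes a *set* of canonical herbs; the binary herbs ×
prescriptions incidence matrix enforces de-duplication structurally.
Occurrence totals are therefore post-de-duplication counts.

## Frequency and attribute profiling

`herb_frequency()` reports per-herb prescription counts and relative
frequencies. `attribute_profile()` distributes the occurrence mass over an
attribute's levels: a herb prescribed 100 times contributes 100 to each
level it carries. The weighting is by occurrence count because that is the
arithmetic under which published category tables are internally consistent
(e.g. a category holding 1233 of 4123 occurrences has rate 29.91 %); an
unweighted per-herb mode (`weighted = FALSE`) is available but not the
default. Property and action category are single-valued, so their weighted
counts partition the total exactly and rates sum to 100 % up to rounding;
tastes and meridians are multi-valued and may exceed it.

Reported values are rounded **half away from zero** (`round_half_up()`),
3 decimals for relative frequencies and 2 for percentage rates and rule
metrics, matching the convention of the summary tables this output style
mirrors; base R's round-half-even would disagree on exact-.5 boundaries.
Rounding is applied only at reporting time — thresholds always compare
unrounded values.

## Association rules

`frequent_itemsets()` is a level-wise Apriori search: frequent k-itemsets
sharing a (k−1)-prefix are joined into (k+1)-candidates, candidates with
any infrequent k-subset are pruned before counting, and the search stops
when a level is empty. No maximum itemset length is imposed. Support uses
the integer threshold `count ≥ ⌈min_support × N − ε⌉` with a tiny ε
guarding against floating-point representation of the product.

For a rule X ⇒ Y, support is σ(X∪Y)/N, confidence σ(X∪Y)/σ(X), and lift is
confidence divided by the **relative frequency** σ(Y)/N of the consequent.
The lift denominator deserves a note: written as "confidence / σ(Y)" it is
dimensionally a count, but only the relative-frequency reading reproduces
conventional printed lifts (0.8851 / 0.7726 = 1.15), so that is what the
package computes. Consequents default to single herbs (`max_rhs = 1`) —
the form in which herb pairs are read clinically — and are configurable.

The default screening thresholds, support ≥ 0.30 and confidence ≥ 0.85,
are the customary values for formula analysis at a few hundred
prescriptions: low enough to admit the habitual pairs, high enough to
exclude co-occurrence explainable by ubiquity alone.

`brute_force_frequent()` enumerates all subsets of universes up to 20
items and exists purely as an independent oracle; the test suite checks
the level-wise miner against it on hundreds of random databases.

`rule_consistency_report()` addresses a practical nuisance: published rule
tables are sometimes not internally reproducible at the printed precision.
Given reported metrics and marginal counts it reconstructs the implied
integer joint count from each support, recomputes confidence (for
single-herb antecedents) and lift (from the reported confidence), and
flags irreproducible rows. For the bundled 30-row reference table this
flags three confidence values and four lift cells; the package reproduces
the metric definitions exactly and enumerates the discrepancies rather
than matching them.

## Hierarchical clustering

Herbs prescribed strictly more than `cluster_min_count = 30` times are
clustered on the Euclidean distance between their binary incidence rows
(for binary vectors, squared distance = number of prescriptions containing
exactly one of the two herbs). Binary incidence is the natural reading of
"each herb is a variable" over prescriptions; dosage-weighted or
frequency-weighted representations are out of scope.

The linkage is a genuine free choice — published dendrograms of this kind
rarely state it. The default is Ward (`ward.D2`, well-defined for
Euclidean input and the common choice for compact clinical clusters), with
complete and average linkage as options; all three are monotone, so merge
heights are nondecreasing. Results should be reported with the linkage
named. Ties between equally close pairs merge the lowest-index pair first
(the behavior of `stats::hclust`, verified in the test suite), so
dendrograms are reproducible. The default cut at `k = 5` follows the
convention of reading formulae as a handful of syndrome-oriented groups;
no automatic k selection is attempted.

## Co-prescription network and backbone

The weighted graph has herbs as nodes and pair co-occurrence counts as
edge weights. The multiscale backbone (disparity filter) scores edge
(i, j) from endpoint i with degree k_i ≥ 2 and strength s_i as
α_ij = (1 − w_ij/s_i)^(k_i − 1) — the probability, under a uniform random
partition of s_i over k_i edges, of a normalized weight at least as large.
An edge is retained when significant from **at least one** endpoint (OR
rule, the common convention; an AND rule is available). A confidence level
of 0.95 corresponds to α = 0.05 per edge; no multiple-testing correction
is applied across edges, matching common practice for this filter. A
degree-1 endpoint puts its whole strength on one edge and yields no test;
an edge whose *both* endpoints have degree 1 is untestable and retained by
convention, flagged `degree_one` in the output.

`core_subgraph()` applies a degree threshold (default 36) to the **raw**
graph after filtering — "core herbs" are those broadly co-prescribed in
the original data whose connections survive the significance filter. The
threshold is exposed because its natural value depends on the herb
universe; the recovery experiment below uses 20 against a 48-herb
universe.

## Synthetic generators and what they show

Three generators support validation; all draw from a single seeded RNG per
call and restore the caller's random state.

* `generate_independent()` — every herb enters every transaction
  independently with its marginal probability. The null model: any rule
  structure found here is an artifact. The test suite checks that
  marginals in the 0.20–0.45 range yield no rules at 0.30/0.85.
* `generate_template_mixture()` — each transaction draws a latent template
  and includes each template herb with its inclusion probability, plus
  background noise herbs. Templates emulate syndrome-driven
  co-prescription: herbs exclusive to a template form planted clusters;
  herbs shared by all templates form a planted core. Ground truth is
  returned alongside the data.
* `build_exact_fixture()` — a deterministic circular interval arrangement:
  transactions are points on a ring, each herb occupies a contiguous arc
  of length equal to its marginal count, and each constrained pair's arcs
  are offset to overlap in exactly the requested number of transactions.
  The construction is exact for any constraint set forming a forest and
  respecting the Fréchet bounds max(0, c_A + c_B − N) ≤ c_AB ≤
  min(c_A, c_B); cyclic constraint graphs are rejected rather than solved,
  since three mutual constraints can be jointly infeasible in ways no
  interval arrangement detects. This realizes count configurations
  reconstructed from published marginal/support tables, so printed metrics
  can be recomputed from actual data.

Validation problem sizes: the miner-vs-oracle equivalence runs on 200
random databases of up to 12 items × 40 transactions; the recovery
experiments use 2000 transactions with 5 templates of 6 herbs (clustering,
adjusted Rand index ≥ 0.9 at k = 5) and 5 templates of 5 herbs sharing an
8-herb core at inclusion 0.95 (core recovery, exact), at fixed seeds.
These sizes give comfortable statistical margins — the planted signal is
many standard errors above noise — while keeping the suite quick.

What passing these tests does *not* show: real prescription data have
within-patient correlation across visits, secular drift in prescribing,
dosage variation, and herb marginals that are not independent of the
latent syndrome mix. The generators emulate none of these; they validate
the algorithms' correctness, not robustness to clinical messiness.

## Degenerate inputs and numerical conventions

* Empty record sets, all-unknown prescriptions, and empty databases raise
  typed errors (`herbminer_empty_input`, `herbminer_unknown_herb`, …).
* Item ordering is lexicographic under C collation everywhere, so outputs
  are locale-independent and byte-identical across runs.
* `min_support`/`min_confidence` of 0 are rejected (support 0 would admit
  every subset of the universe).
* Transactions that contain no herbs are representable (the exact-count
  fixture may produce them) and simply contribute zeros.
* All thresholds compare unrounded values; rounding is cosmetic and
  half-away-from-zero at documented precisions.

## Knowledge-base content

The bundled `herb_kb.csv` covers 52 herbs (the high-frequency herbs of the
motivating CKD setting plus common companions) with properties, tastes,
meridians and action categories assigned from standard materia-medica
references, and one worked compound decomposition. It is configuration,
not code: analyses of other corpora should extend or replace it, and the
loader validates any KB against the controlled vocabularies
(`herb_properties`, `herb_tastes`, `herb_meridians`, `herb_categories`).

## Known limitations

* Prescription-level transactions ignore patient-level dependence.
* The disparity filter tests each edge marginally; no FDR control.
* Cluster count k and the core degree threshold are user choices; the
  package offers no automatic selection.
* The exact-count fixture builder handles pairwise constraints on a
  forest only; it cannot realize higher-order (triple-wise) constraints.
* Chinese-character input is out of scope; the KB operates on romanized
  and Latin pharmaceutical names.
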