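---
title: "Quantifying structural disorder in vesicle trafficking proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural disorder in vesicle trafficking proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtdisorder)
```

## The problem and the model

The three main vesicle trafficking routes — clathrin-mediated, COPI and
COPII — share a common architecture (coat, adaptors, membrane-fusion
machinery) but differ in plasticity and evolutionary adaptability.
One structural property suspected to drive that difference is intrinsic
disorder: protein segments that function without a fixed tertiary
structure. `vtdisorder` quantifies disorder across such protein cohorts
from per-residue predictor output and relates it to route membership,
moonlighting interactions, tissue-specific exons and ortholog
divergence.

The package deliberately consumes predictions rather than making them:
disorder and binding propensities arrive as plain-text per-residue score
tracks in the IUPred/ANCHOR dialect (one residue per line; scores in
[0, 1]). Re-implementing those energy-based predictors is out of scope;
a toy sliding-window propensity predictor (`propensity_track()`) is
included purely as a stand-in for generating plausibly shaped tracks in
tests and examples.

## Per-protein metrics and their conventions

A residue is classified *disordered* (or *binding*) when its score is at
least the threshold (default 0.5, the standard cut-off). Two choices
here are conventions, not facts, and are therefore configurable:

* **Ties at the threshold count as disordered** (`score >= threshold`).
  Predictor documentation does not fix the boundary case; we pick the
  inclusive reading and expose `threshold` in `binarize_track()` and
  `summarize_protein()`.
* **Transmembrane exclusion.** Residues inside annotated TM segments are
  removed from every metric — numerator and denominator alike — because
  hydrophobic membrane-embedded stretches systematically fool
  sequence-based disorder predictors. Exclusion also *interrupts
  disordered runs* (the no-join policy): a membrane-spanning helix
  physically separates the disordered stretches on its two sides, so a
  run may not continue across it. Because this is a modelling choice,
  `find_runs(join_over_excluded = TRUE)` provides the alternative where
  runs continue across excised residues (which still contribute nothing
  to run length).

From the binarized, masked track we compute, per protein of effective
length $L'$:

* disorder content $d.c. = n_\mathrm{dis} / L'$;
* LDR residue ratio at $k$: residues in maximal disordered runs of at
  least $k$ residues divided by $L'$, for $k \in \{30, 50, 100\}$
  (`k_values`);
* DBR residue ratio: the same construction on the binding track with
  minimum run length `dbr_min_len` (default 6 residues).

The DBR minimum length deserves a note: ANCHOR-class predictors apply
internal region filters whose details are not restated in the analyses
that consume them, so *region counts* (`n_dbr`) are convention-dependent
and should be compared only under a stated convention. Ratios are much
less sensitive to the choice. A protein with no binding track has its
DBR fields set to `NA` ("unavailable"), never silently to zero. Proteins
shorter than $k$ simply have `has_ldr(k) = FALSE`.

## Cohort statistics

`group_summary()` and `ldr_prevalence()` aggregate per-group means,
medians (midpoint convention for even n) and LDR-prevalence fractions. A
protein annotated to several routes is counted once per route — per-route
tallies treat routes independently.

`rank_sum_test()` compares two cohorts' metric values. The exact
permutation null is used for tie-free samples with $n_1 + n_2 \le 12$;
beyond that, the normal approximation with midrank ties, tie correction
and continuity correction. Samples whose pooled values are all identical
are degenerate: p = 1 with a flag, rather than an error, so screening
loops do not halt on pathological groups.

`enrichment_test()` contrasts a group's flagged fraction with a
whole-proteome reference via the hypergeometric (Fisher) tail. The 2×2
table uses the reference counts *as printed* — the whole proteome
including the group — because published reference rows are almost always
whole-proteome values; `exclude_group = TRUE` gives the disjoint
construction. The background size is a runtime parameter, never a
constant: published proteome sizes vary between releases (and sometimes
between tables of the same work), so hard-coding one would bake in an
inconsistency.

`compare_pathways()` reports raw p-values (matching the practice of the
analyses it reproduces) and emits a Benjamini–Hochberg column alongside,
per test family, for transparency. The default alternative is two-sided
for rank-sum comparisons and one-sided (`greater`) for enrichment;
every result records the alternative used.

`select_highly_disordered()` implements the highly-disordered selection
rule: disorder content ≥ 70 %, or LDR residue ratio at $k=30$ reaching a
cut-off that combines a cohort-relative criterion (mean + 2 sd) with an
absolute one (50 %). The phrase "mean plus two standard deviations or
50 %" admits two readings; we take the permissive one — the cut-off is
the *minimum* of the two, so either criterion suffices — and expose
`cutoff_rule = "max"` for the strict reading.

`classify_domain_context()` labels each Pfam-style domain by whether the
regions between it and the termini are extended disordered flanks
("structured islands"): a flank qualifies with ≥ 30 countable residues at
≥ 70 % disorder (`flank_min_len`, `flank_disorder_min`). The island label
names the disordered side(s): a protein that is one N-terminal domain
plus a long disordered tail is `island_C`.

## Interaction filtering

Sequence identity uses the CD-HIT convention: matches of an optimal
global alignment (match 1, mismatch 0, no gap penalty — i.e. the longest
common subsequence) divided by the *shorter* sequence length. This is
deliberately permissive: a perfect substring scores 1.0, which is what a
redundancy filter wants. The cascade in `filter_offpathway()` is
confidence (≥ 0.9) → identity to any pathway protein (> 70 % removed) →
greedy clustering of each source's surviving partners at the same
threshold (longest-first, lexicographic tie-break, founder represents) →
exclusion list. The exclusion list externalises manual curation; an
example list of promiscuous small GTPases ships in
`inst/extdata/exclusion_gtpases_example.txt`, documented rather than
hard-coded. Off-pathway totals count (source, partner) *edges*; unique
partner counts are reported alongside, since several sources can share a
partner. Route means/medians are taken over all proteins annotated to the
route, counting zero for proteins with no surviving partner (the
alternative — only proteins with ≥ 1 partner — is not what a
per-protein moonlighting propensity should mean).

## Tissue-specific exons

Exons qualify as tissue-specific at switch score ≥ 0.25 (`min_switch`);
non-coding records are excluded with a message. Mapping a CDS exon to
protein coordinates needs a rule for codons split across exon
boundaries: we use the **codon-majority rule** — a residue belongs to the
exon containing at least two of its three codon bases. It is
deterministic, symmetric between the exon's two ends, and reduces to the
obvious mapping for in-frame exons. Two consequences are accepted
explicitly: an exon contributing a single base claims no residue (empty
span, flagged), and a codon split one base each across three exons is
claimed by no exon, so exon spans tile the protein except at such
three-way splits. The first-base rule (`rule = "first_base"`), which
tiles exactly, is available. Direct `protein_span` input bypasses mapping
so published span tables can be consumed verbatim.

TSE disorder fractions use the same TM-excluded denominator as every
other metric ("any disorder metric" includes these); whether published
per-exon fractions did the same is unstated, so the consistent
convention is used and documented here. DBR association distinguishes
regions overlapping the exon span from regions disjoint from it but
within the 5-residue boundary neighbourhood (`flank`), which are likely
still affected by the exon's inclusion.

## Ortholog comparison

`compare_orthologs()` takes disorder contents of human–yeast pairs,
requires at least one member above 30 % disorder content
(strictly greater; boundary cases flagged) to enter the comparison, and
calls a pair *similar* when the difference is under 5 *percentage
points* — the reading consistent with treating a 71.4 % vs 74.4 % pair
as similar; the relative-difference reading would be far stricter.
Below-threshold pairs stay in the output but not in the category
tallies.

## The synthetic-data generator

`synth_cohort()` exists so that every pipeline stage can be exercised
with known ground truth. It emulates:

* proteins built from planted ordered/disordered/TM segment
  architectures (one contiguous disordered block per protein, yielding
  realistic LDRs), with DBR sub-segments inside disordered blocks;
* score tracks equal to ground-truth labels (centres 0.8/0.2) plus
  Gaussian noise of sd `noise_sd` clipped to [0, 1] — at the noise
  levels used (sd ≤ 0.1) clipping is negligible and threshold
  classification errors are rare ($P(0.3/\sigma)$-tail);
* cohorts with specified per-group mean disorder content and
  between-group effect sizes; the default study contrast plants means
  0.28 vs 0.09 with dc sd 0.08 and n = 30 per route, mirroring the
  clathrin-vs-COPI difference, at protein lengths 120–180 (kept modest
  so the full suite runs quickly; the contrast is length-invariant);
* sequences with label-biased composition (disorder-promoting residues
  in disordered segments), so the toy propensity predictor correlates
  with ground truth.

By default no TM segments are planted (`tm_prob = 0`): a TM helix carved
out of an ordered block removes residues from the denominator and
inflates realized disorder content above the planted target, which would
blur parameter-recovery checks. Tests that exercise masking set
`tm_prob` explicitly.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: predictor errors are not independent
Gaussian noise (they are sequence-correlated and systematically biased
at domain boundaries); real disorder is not one contiguous block per
protein; real cohorts have heavy-tailed length distributions and
route-correlated composition. The generator validates the *pipeline
arithmetic and statistics*, not the predictors.

## Numerical and degenerate-input choices

* Intervals are 1-based inclusive everywhere; half-open conversions are
  internal only.
* Sequences may contain X/B/Z/U, scored like any residue.
* `write_table()` renders floating-point cells with two decimals
  (percentage columns scaled ×100), so identical rows re-write
  byte-identically.
* A protein that is entirely transmembrane has undefined metrics
  (`NA` + warning), as does an exon span wholly inside a TM segment.
* Greedy clustering ties (equal length) break lexicographically by id,
  making clustering deterministic.
* All generator outputs are seeded and byte-reproducible.

## Known limitations

Absolute reproduction of published cohort tables requires the original
sequence release and predictor outputs, which the package does not
bundle; the test suite instead verifies the machinery against
independent oracles (brute-force run scans, exhaustive rank
permutations, direct hypergeometric summation) and against the published
per-protein arithmetic that *is* self-contained (worked disorder-content
ratios, interaction-report totals, boundary DBR calls). Pairwise
identity is alignment-convention-dependent; values from other tools will
differ in the second decimal. The rank-sum normal approximation is
conservative for very small tied samples; for n ≤ 12 tie-free the exact
null is always used.
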