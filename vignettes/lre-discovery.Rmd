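---
title: "Methods: tri-loop response-element discovery and validation statistics"
author: "lrescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-loop response-element discovery}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrescan)
```

## The structural model

A response element is modelled as a local tri-loop hairpin: a stem of
consecutive base pairs closed around an unpaired loop of exactly three
nucleotides. Two structural constraints define a valid element — the
third loop nucleotide must be a purine (A or G), and the loop-closing
stem pair must be U–A or C–G. We read that pair with the 5′-strand base
first, so "U–A" means U on the 5′ arm; the orientation genuinely matters
and the alternative reading (A on the 5′ arm) is rejected by
`classify_lre()`. This reading follows the loop-proximal emphasis of the
usual hairpin diagrams and can be changed only by editing the predicate,
deliberately: it is a structural definition, not a tuning knob.

Enumeration is purely local: from every possible loop position the stem
is grown outward pair by pair while consecutive pairs satisfy the
pairing policy (canonical A–U/U–A/G–C/C–G anywhere; G–U/U–G wobble only
in non-closing positions, and only when `allow_wobble = TRUE`). At most
one hairpin is reported per loop position — the maximal stem, capped at
`max_stem` — and stems shorter than `min_stem` are discarded. We chose
local enumeration over thermodynamic folding because the structural
definition above is local; no folding engine is invoked and no
minimum-free-energy model is implied. Users who want folding-informed
scans can pre-filter candidate regions and pass them as separate FASTA
records. Bulged stems are not considered.

Stem bounds default to `min_stem = 3`, `max_stem = 8` base pairs. These
are package choices: three pairs is the shortest stem that plausibly
forms a stable closed loop at physiological temperature, and pairs
beyond eight contribute little discrimination while quadratically
inflating the candidate space. Both are ordinary arguments of
`lre_scoring_model()`.

## Scoring and categories

Each hairpin scores as a sum of independent per-position contributions:
the three loop nucleotides, the identity of the closing pair, and each
non-closing stem pair (position-independent pair weights, G–C > A–U >
G–U). The shipped table is an explicit stand-in — the position-weight
table of the original binding-strength model was never published — with
two calibration properties enforced by tests: a minimally valid element
reaches the lowest category threshold, and an all-optimal element with a
full-length stem exceeds the highest. Any table can be supplied as a
named vector or YAML file; all scoring semantics (absent keys contribute
zero; determinism) are table-independent.

Scores are binned at the four published twofold thresholds 0.225, 0.45,
0.9, 1.8 into minimal / weak / medium / strong. Lower bounds are
inclusive — forced by the requirement that four printed thresholds
define four categories — so doubling any score in [0.225, 1.8) advances
the category by exactly one step, a property the tests exercise over a
dense grid.

Overlapping sites within a UTR are resolved greedily: highest score
first, ties broken by leftmost start, discarding any site that overlaps
an accepted one. The original analysis does not state its
de-duplication rule; greedy-by-score is the simplest rule that never
discards a stronger site in favour of a weaker one, and it is
deterministic. Coordinates are 0-based half-open internally and in BED
output, 1-based closed nowhere except human-readable prints.

## Per-mRNA aggregation and the discovery funnel

The predicted binding score of an mRNA is the sum of its retained site
scores, each multiplied by a UTR-location weight (`five_prime`,
`three_prime`; both default 1). The binding strength is known to depend
on the number of elements and their UTR location, but no aggregation
formula was published; the weighted sum is the simplest aggregate
consistent with both dependencies, and category-count scoring is
recoverable as the special case of setting each site score to its
category midpoint. No saturation cap is applied — whether the original
per-mRNA score saturates with many elements is unknown — so scores are
additive over disjoint site sets, which the tests verify.

Candidate discovery applies four commuting set filters with full
per-transcript audit flags: RIP enrichment ≥ `min_rip_fold` (default
4-fold, i.e. log2 ≥ 2), membership in the user-supplied
germline-expressed set, at least `min_lre_count` elements (default 2,
the minimum needed for repression) across both UTRs, and absence from
the user-supplied OMA-RIP-enriched set. "At least two LREs" counts
sites of any category by default (`counted_categories` restricts this);
significance of OMA enrichment is delegated entirely to the input list.
Both gene sets are opaque inputs because neither the germline-expression
source nor the OMA-RIP threshold used originally is recoverable.

## Validation statistics

*qPCR.* `ddcq_fold_change()` implements 2^−ΔΔCq with per-replicate
ΔCq = Cq(target) − Cq(reference), ΔΔCq as the difference of condition
means, and an unpaired t-test on the per-replicate ΔCq values. Welch's
unequal-variance form is the default — the original analysis does not
say whether variances were pooled — with `var_equal = TRUE` for the
pooled variant. The statistic is undefined for zero-variance (noiseless
simulated) input; the fold change is still returned with `NA` for t and
p. `standard_curve_quantify()` fits the dilution line by least squares
and reports amplification efficiency 10^(−1/slope) − 1. Ratios of
condition means (`condition_ratio()`) propagate the coefficient of
variation of both groups and test per-replicate ratios against 1, the
convention used when mutant/wild-type ratios are plotted against a unit
line; raw ratios, not log-ratios, are tested.

*Gene-set overlap.* `hypergeometric_overlap()` evaluates the upper tail
P(X ≥ k) through `phyper(..., log.p = TRUE)`, i.e. in log space, because
transcriptome-scale universes (N ≈ 2 × 10⁴) produce p-values around
1e−30 where naive summation underflows. The tests check it against
naive factorial arithmetic for every configuration with N ≤ 20.

*Rank-sum test.* `rank_sum_test()` enumerates all
`choose(n + m, n)` group labelings of the pooled (possibly tied) values
whenever that count is ≤ 20 000 and reports the exact two-sided
p = 2·min(tail probabilities) capped at 1; above the ceiling it uses the
normal approximation with tie and continuity corrections, and the method
used is always reported. The enumeration ceiling trades exactness
against runtime: 20 000 labelings cover all n + m ≤ 12 designs and all
reporter-assay group sizes used here (7–10 animals per strain) while
keeping the worst case to a few milliseconds. On tie-free inputs the
exact path reproduces `wilcox.test(exact = TRUE)`; with ties — common in
rank data — it still enumerates, which `wilcox.test` cannot.

*Fluorescence ratios.* `fluorescence_ratio()` normalizes per-animal mean
oocyte intensity by the mean of reference areas in the distal gonad, and
can drop the final oocyte entry per animal — the ovulating (−1) oocyte,
where the repressor is already degraded, is conventionally excluded.
Group comparisons use the rank-sum test above. Image segmentation and
intensity extraction are out of scope; the input is a tidy table.

## What the synthetic data does and does not emulate

`make_cohort()` generates background UTRs i.i.d. from a configurable
base composition (uniform by default, which keeps chance-hairpin rates
analytically estimable; an AT-rich setting mimicking nematode UTRs is
one argument away), plants a known number of elements of known category
into the 3′ UTRs of a designated target subset (non-overlapping, ≥ 5 nt
from record edges to avoid truncation artifacts), and draws RIP
enrichment from Normal(μ = 3, σ) for targets and Normal(0, σ) otherwise
(σ = 0 in the noiseless configuration). Gene sets are constructed so
that in the noiseless configuration the planted targets are exactly the
funnel's survivors, and every cohort ships a machine-readable truth
table sufficient to predict the candidate set. Fragment generation is a
closed loop: each planted fragment is rescanned before use and must
yield exactly one site of the requested category at the planted
position.

Real data differ in ways the generator deliberately ignores: UTRs are
not i.i.d. (composition bias, repeats, conserved structure), RIP
enrichment is not two-component Gaussian, expression sets are noisy
annotations, and real elements co-occur with other motifs. Passing the
planted-recovery tests therefore demonstrates correctness of the
*pipeline logic*, not discovery power on biological sequence. In
particular the defaults cannot reproduce the original study's candidate
count, which depended on an unpublished weight table and unpublished
input tables.

Problem sizes in the shipped tests were chosen to keep the full suite
under a minute of scanning: 1 000 random sequences of ≤ 200 nt for
scanner–oracle equivalence, a 500-transcript / 20-target noiseless
cohort for planted recovery, 500-transcript cohorts for the null and
coupled correlation checks, 1 000 replicate simulations for t-test
calibration, and 300 seeds for the overlap-generator calibration.

## Degenerate inputs and numerical notes

Sequences shorter than `2·min_stem + 3` yield an empty table, not an
error; invalid characters are input errors naming the record and offset;
DNA input (T) is transliterated to U at load, and scanning the DNA form
yields byte-identical sites. All-tied rank-sum input returns p = 1 with
a warning. Standard curves reject non-negative or near-zero slopes.
Negative scores are contract violations. All generators restore the
caller's RNG state, so seeded calls are referentially transparent.

## Known limitations

- The weight table is a calibrated stand-in; absolute scores are not
  comparable to the original model's, only the category machinery and
  pipeline logic are.
- No secondary-structure folding: elements occluded by long-range
  structure are still reported, and bulged stems are missed.
- The funnel treats expression and OMA sets as oracles; garbage lists in,
  garbage candidates out.
- The per-mRNA score has no saturation, so mRNAs with many weak sites
  can outscore mRNAs with few strong ones.
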