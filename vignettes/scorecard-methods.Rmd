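---
title: "The scorecard method: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scorecard method: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descorecard)
```

## The model

A scorecard compares two differential-expression contrasts at once. Each
shared gene is a point $(x, y)$ where $x$ and $y$ are its log2
fold-changes in the two contrasts. Two thresholds
$0 < t_\mathrm{low} < t_\mathrm{high}$ band each axis into *central*
($|v| < t_\mathrm{low}$), *moderate*
($t_\mathrm{low} \le |v| < t_\mathrm{high}$) and *extreme*
($|v| \ge t_\mathrm{high}$); a value exactly at a threshold belongs to
the outer band, so the bands are half-open and exhaustive for finite
input. The axis-category pair maps to a lettered region of interest
within the gene's quadrant:

| x-axis | y-axis | region |
|---|---|---|
| extreme | extreme | A |
| extreme | moderate | C |
| moderate | extreme | B |
| extreme | central | D |
| central | extreme | E |
| moderate | moderate | M |
| moderate | central | S |
| central | moderate | R |
| central | central | (not reported) |

Letters C, D, S are x-dominant and B, E, R y-dominant. The assignment of
letters to axes is a convention; because published figures differ only
in their color keys, `scorecard_config(swap_letter_axes = TRUE)` flips
the convention (B↔C, D↔E, S↔R) without touching the geometry. The
classifier is total and deterministic, and transposing the axes swaps
exactly those letter pairs together with quadrants Q2↔Q4 — a property
the test suite checks exhaustively on a boundary grid.

Three modes control the detail level. `full` reports all eight letters;
`standard` masks the moderate-only letters M, S, R and reports only
regions involving an extreme axis; `fourway` is the classic four-way
plot: a single threshold ($t_\mathrm{low}$), quadrant membership only.
At equal thresholds the reported sets nest: standard ⊆ full ⊆ fourway.
The significance machinery is applied identically in all three modes;
whether a plain four-way plot should filter by significance at all is
genuinely open, and applying the same filter everywhere keeps the mode
comparison meaningful (a gene that disappears when moving from fourway
to full did so because of geometry, not because the filter switched on).

## Significance filtering

Only genes with $p \le \alpha$ on the tested axes are reported
($p = \alpha$ passes, matching the usual "$p \le 0.05$" phrasing). The
default policy, `non_central_axes`, tests every axis whose category is
moderate or extreme and exempts central axes. This choice is forced by
regions D and E: a gene flat on one axis almost never has a significant
p-value there, so a rule demanding significance on both axes would empty
exactly the regions that capture condition-exclusive activity. The
stricter `both_axes` and looser `either_axis` policies are available for
sensitivity analyses.

Missing p-values fail their axis test by default (`missing_p = "fail"`),
the conservative reading. When contrasts are derived from a
condition-by-gene expression table with `derive_pairwise_comparisons()`
there are no p-values at all; `missing_p = "pass"` disables the filter
for those axes so that the derived workflow remains usable. This is a
deliberate extension: with only the three axis policies and hard-failing
missing p, an expression-derived study could never report any gene.

## Parameters

* `t_low`, `t_high` — log2 fold-change units. Defaults 2 and 3 (i.e. a
  4-fold inner and 8-fold outer change, multiplication factor 1.5),
  typical for antibiotic-exposure biofilm studies; dense genome-wide
  designs may prefer 2 and 4 ($\times 2$) with a stricter $\alpha$ such
  as 0.001 to limit the number of outliers reported. `t_high` may be
  given directly or via `factor`, since both phrasings are common.
* `alpha` — applied to p-values assumed already multiplicity-adjusted
  upstream (e.g. Benjamini–Hochberg); the package deliberately performs
  no adjustment of its own.
* `pseudocount` (in `derive_pairwise_comparisons()`) — default 1,
  standard for FPKM-scale ratios; it bounds fold-changes when one
  condition is zero and forces $\log_2(1) = 0$ when both are.
* `fc_cap` (in `read_comparison_table()`) — non-finite or out-of-range
  log2 fold-changes from upstream zero-denominator divisions are clamped
  to ±20 and counted in the load report, keeping classification total
  without silently inventing data.

## Numerical and degenerate-input choices

Zero coordinates count as positive for quadrant assignment; this only
affects D/E/S/R genes sitting exactly on an axis. Genes present in one
comparison but not the other are dropped with accounting (no imputation
rule is defensible without replicate-level data); the drop counters are
exhaustive, so `entries + missing_partner + central + not_significant`
always equals the size of the union of the two gene sets. Ranking ties
in the difference table break by input pair order then gene id, and
every exported table has a deterministic row order, so identical runs
are byte-identical. Keyword counting is case-insensitive substring
containment over reported entries (with repetition across scorecards),
the simplest rule consistent with counting recurring terms over all
gene descriptions of a study; the difference metric is
$|x - y|$ on the log2 scale — an assumption, since published difference
tables do not define the column formally, but the only scale on which
the two axes are commensurable.

## The synthetic fixture generator

`generate_fixture()` emulates the wide per-comparison CSV of a real
study with planted ground truth. Planted genes are placed at band
midpoints plus a jitter strictly smaller than half the narrowest band
width, which makes their cell membership certain rather than merely
probable — recovery tests are exact, not statistical. Each planted gene
exists only in the two comparisons of its target pair, so its reported
location is known without re-deriving it through the classifier; noise
genes are central and non-significant everywhere (p drawn above
$1.2\alpha$, significant genes below $0.8\alpha$, leaving a guard band
around $\alpha$). Default sizes (thousands of noise genes, tens of
planted genes per scorecard) mirror the scale of genome-wide biofilm
studies qualitatively.

What the generator does *not* emulate: count-level noise, library-size
and dispersion effects, correlated fold-changes between contrasts
sharing a control, or p-values computed from replicates. Passing the
recovery tests therefore demonstrates the correctness of
classification, filtering, aggregation and reporting — not robustness
of upstream differential-expression inference, which is out of scope
(inputs are taken as released by a study's authors).

The longitudinal generator scripts a region letter (or absence) per
time point for selected genes, emulating time-course designs where a
gene may be moderately expressed at an early time and extremely
overexpressed thereafter; `track_regions_over_series()` must recover
the script exactly.

## Verification problem sizes

The package's own verification (tests and `scripts/acceptance.R`) uses
the combinatorial anchors of the two canonical designs (4 comparisons →
6 scorecards; a 6-condition design's 15 contrasts → 105), an
independent brute-force inequality classifier checked against
`classify_point()` on 10,000 uniform points in $[-6, 6]^2$ and an
11×11 sign/boundary grid for threshold pairs (2, 3) and (2, 4), and a
planted fixture with 5 genes in each of the 32 quadrant-region cells of
all 6 scorecards plus 2,000 noise genes, recovered at 100% with zero
false reports in all three modes under all three significance policies.
These sizes keep the whole suite under a minute while exercising every
band boundary and every aggregation path.

## Known limitations

* No automatic threshold selection; thresholds are scientific choices.
* No density-based decluttering of crowded scatters; label decluttering
  is a deterministic top-k by distance from the origin.
* Annotation keyword matching does no stemming or synonym expansion.
* The CSV reader expects one wide table per study; per-contrast files
  must be joined upstream.
* Tables are written as CSV (one file per table); figures as
  PNG/SVG/PDF via ggplot2.
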