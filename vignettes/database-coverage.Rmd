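---
title: "Measuring literature-database coverage of randomized clinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring literature-database coverage of randomized clinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcover)
```

## The problem

A systematic review stands or falls with its literature search. Individual
bibliographic databases index overlapping but incomplete slices of the
literature, so reviewers search several databases, pool the exports, remove
duplicates, and screen what remains. Two quantities are in tension: the
*coverage* of the combined search (what fraction of the truly eligible
studies it retrieves) and the *screening load* (how many raw records a
human must look at). refcover quantifies both, per database and per
database combination, for any topic where a reference set of eligible
studies can be established by searching widely and screening once.

The package grew out of the study design used for evaluating database
coverage of randomized clinical trials on central serous chorioretinopathy
(CSC), a retinal disease with an active trial literature: search 12
databases, pool and deduplicate the records, screen the unique publications
against eligibility criteria, then go back and ask, for every database and
pair of databases, how much of the eligible set it would have found.

## The diagnostic model

Let $E$ be the set of eligible unique publications identified across all
databases, $N$ the pooled number of records (all exports concatenated,
duplicates included), and for database $d$ let $y_d$ be its yield (its
record count in the pool) and $k_d$ the number of publications in $E$ it
indexes. The 2x2 retrieval table for $d$ is

* $TP = k_d$, $FN = |E| - k_d$ (counted over *unique* publications),
* $FP = y_d - k_d$, $TN = N - y_d$ (counted over *pooled* records,
  duplicates included).

The mixed counting is deliberate: relevance is a property of a
publication, but screening effort is a property of raw records. A
consequence is that per-database totals $TP+FP+FN+TN = N + |E| - k_d$
differ across databases; refcover preserves this convention rather than
normalizing it away, because it reflects the workload a reviewer actually
faces. The estimators are

$$\widehat{Se}_d = \frac{TP}{TP+FN}, \qquad
  \widehat{Sp}_d = \frac{TN}{TN+FP}, \qquad
  \widehat{Ac}_d = \widehat{Se}_d\,\pi + \widehat{Sp}_d\,(1-\pi),$$

with prevalence $\pi = (TP+FN)/(TP+FP+FN+TN)$; the accuracy expression
reduces algebraically to $(TP+TN)/\text{total}$, and the package asserts
this identity to machine precision in its tests. Sensitivity here is
identical to coverage and to recall. Accuracy should be read with care: a
database returning nothing has $Sp = 1$ and, at low prevalence, high
accuracy. The `summary()` output therefore leads with sensitivity.

### Confidence intervals

Interval estimates use the exact Clopper-Pearson construction from beta
quantiles: for $k$ successes of $n$,
$$\big[\,B_{\alpha/2}(k,\,n-k+1),\; B_{1-\alpha/2}(k+1,\,n-k)\,\big],$$
with the conventional endpoints 0 (at $k=0$) and 1 (at $k=n$), so the
degenerate row "0 of 76 trials covered" gets the informative interval
$(0, 1 - (\alpha/2)^{1/76}) \approx (0\%, 5\%)$ rather than the
zero-width Wald interval. Exactness (guaranteed at-least-nominal coverage)
is what one wants with $n = 76$ eligible trials and coverage counts as
small as 0 or 4. The accuracy interval is an exact binomial interval on
$TP+TN$ of the table total; since accuracy is a derived quantity, no
small-sample interval is canonical, and the choice is flagged here as a
reporting convention. The test suite validates the routine against
`binom.test()` (an independent implementation), against the $k=0$ closed
form, and with a seeded simulation of interval coverage.

Displayed percentages are rounded half-up to integers; all stored values
keep full precision.

## Duplicate detection

Reference managers do not document their deduplication rules, so refcover
declares its own, simple enough to reason about and aggressive enough for
export noise. Records link when they share a non-missing DOI; or share an
exact key of normalized title, year and first-author family name; or have
normalized-title similarity at or above a threshold (default 0.90,
normalized Levenshtein) with equal years. Clusters are transitive closures
of links; a conflict between two non-missing DOIs vetoes a fuzzy link,
because DOIs are the strongest identity signal available in exports. Title
normalization lower-cases, folds diacritics, deletes everything but
letters, digits and spaces, and collapses whitespace -- so
"Half-dose  Photodynamic Therapy!" and "half dose photodynamic therapy"
meet on the same key. The default threshold of 0.90 was chosen once, to
catch punctuation/OCR variants while keeping distinct trials with similar
titles (e.g. full-dose vs half-dose protocols) apart; the suite checks the
clustering against a brute-force pairwise/graph-components oracle and
checks that lowering the threshold can only merge, never split.

## Database combinations

A database set is evaluated as a union: a publication counts as retrieved
if any member indexes it. TP and FN again count unique publications; FP
and TN use the *summed member yields* as the screening universe, because
running two searches means screening both exports, duplicates and all
(`universe = "dedup"` switches to unique-record counting for readers who
prefer it). Union sensitivity is non-decreasing in the set -- a property
test -- while specificity degrades as noisy members join.

`minimal_cover()` searches for the smallest sets reaching a target
sensitivity. With up to 15 databases every subset up to `max_size`
(default 3: pairs are the published design, triples a cheap
generalization) is enumerated exhaustively; beyond that a greedy
marginal-coverage heuristic takes over and the result is flagged as such.
Qualifying sets are ordered by size, then screening load, then label --
fully deterministic. Exhaustive results are verified against brute-force
subset enumeration in the tests; the greedy chain is checked never to beat
the exhaustive optimum.

## The synthetic generator

Raw database exports are licensed content and cannot ship with a package,
so every pipeline stage is exercised on generated corpora with planted
ground truth. The generator emulates: a set of unique publications with
synthesized titles (drawn from a domain word pool), years, author lists
and DOIs; an indexing matrix (which databases carry which publication);
one exported copy per (publication, database) pair; per-copy export noise
-- a title perturbation (case flip, punctuation insertion, doubled space)
with probability `duplicate_noise` (default 0.15) and a missing DOI with
probability `doi_missing_rate` (default 0.2, reflecting how patchy DOI
fields are in real exports); and screening labels keyed by canonical
record ids. Two regimes exist: *probabilistic* (each eligible publication
indexed by database $d$ with a stated probability -- used for parameter-
recovery and property tests) and *constrained* (exact per-database counts
planted -- used for the study-scale presets).

What the generator does **not** emulate: indexing lag, language-specific
coverage, within-database duplicate records, retracted/versioned records,
and realistic title collisions between distinct publications (planted
titles are kept distinct under normalization). Passing tests therefore
demonstrate that the pipeline arithmetic and clustering logic are correct
under declared noise, not that the dedup rules would survive every
real-world export quirk.

### Study-scale presets

`study_preset()` reconstructs the published marginals of the 12-database
CSC search: yields (80, 26, 141, 97, 0, 0, 184, 4, 102, 138, 2, 126),
coverage counts of the 76 eligible trials (32, 12, 66, 44, 0, 0, 67, 4,
28, 57, 0, 51), 225 ineligible unique publications, and the constraint
that Cochrane Central and PubMed jointly cover all 76. The publication-
level overlap between databases was never published, so it is *sampled*
subject to those marginals: every preset corpus is a reconstruction, and
anything that depends only on the marginals (per-database sensitivities,
the 141 + 138 = 279 screening load of the Cochrane Central + PubMed pair,
its 100% union coverage) reproduces exactly, while overlap-dependent
quantities (pairwise cells beyond the forced pair) vary with the seed.

The published yield column sums to 900 records although the study reports
848 pooled records, a 52-record discrepancy that the source leaves
unexplained. refcover never hard-codes the printed total: every total is
recounted from the records present. Because one corpus cannot satisfy
both figures, there are two presets: `study_preset()` honours the
per-database yields (pooled size 900; derived TN values exceed the
published ones by exactly 52), and `study_flow_preset()` honours the
screening flow 848 = 547 duplicates + 225 ineligible + 76 eligible,
removing the 52 surplus irrelevant copies by largest-remainder scaling of
the per-database irrelevant yields. Use the former for yield/contingency
structure, the latter for the deduplication ledger.

## Numerical and degenerate-input choices

* Proportions are kept in double precision; only display rounds (half-up
  to integer percent).
* `sensitivity()` with no eligible publications, `specificity()` with no
  irrelevant records, and intervals with $n = 0$ are errors, not NaNs --
  a corpus with no reference set cannot support a coverage claim.
* Empty corpora flow through the pipeline (zero ledger, empty tables);
  zero-yield databases stay visible in every table.
* Union TN is floored at zero (relevant only when member yields exceed
  the pool, impossible for genuine subsets).
* Ties in `minimal_cover()` break by size, then load, then label;
  cluster canonical members are the lexicographically smallest record id;
  both make reports reproducible byte for byte. The run log carries no
  timestamp for the same reason.

## Problem sizes

The test suite runs study-scale corpora (about 850-900 records, 12
databases) for end-to-end checks, 5-6 database corpora of a few hundred
records for oracle comparisons, 50-60 generator replicates for
parameter-recovery checks and 2,000 draws for the interval-coverage
simulation -- sizes chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo standard errors far below the tested
tolerances.

## Limitations

Coverage estimates are conditional on the reference set being complete: a
trial indexed by *no* searched database is invisible to the design, so
sensitivities are relative to the union of the searched databases, not to
the literature in the abstract. The dedup rules are a declared convention,
not a reconstruction of any reference manager. Accuracy inherits the
pooled-universe asymmetry described above and is not comparable across
corpora with different duplicate structures. And the study-scale presets
reproduce published *marginals*; conclusions that depend on unpublished
overlap structure (e.g. exact pairwise specificities) cannot be recovered
from print and are validated only property-wise, against oracles, on
synthetic data.
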