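---
title: "Enrichment analysis of BCT–MoA link corpora: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment analysis of BCT-MoA link corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moalink)
```

## The data model

A coded corpus records, for a set of published behavior change
intervention articles, every author-described hypothesis that a specific
behavior change technique (BCT, one of the 93 BCTTv1 techniques) operates
through a specific mechanism of action (MoA). It is held in three tables
joined on `article_id`: article metadata (`source`), the BCTs coded per
article (`bct`), and one row per link statement (`link`). Each statement
carries three coding flags, stored as their literal 1/2/3 codes:

* `explicitness` — 1 if some inference was needed to code the link, 2 if
  none;
* `grouping` — 1 for a one-technique-to-one-mechanism statement, 2 when
  the statement involved a group of techniques or mechanisms (group
  statements are expanded into pairwise rows at coding time; the flag is
  retained for reporting);
* `empirical_status` — 1 mechanism not measured, 2 measured but the link
  not tested, 3 link tested.

Authors label mechanisms in their own words. Labels are normalized
(case, whitespace, quotes) and mapped onto a fixed registry of 26
constructs — the 14 Theoretical Domains Framework domains plus 12
constructs frequent across behavior change theories — first by canonical
label, then through a small, user-extensible synonym seed (e.g.
*self-efficacy* → *Beliefs about Capabilities*, a documented conceptual
identity). Anything else resolves to `OTHER`: full coder judgment cannot
be automated, and guessing would contaminate the frequency matrix, so
unresolved labels are excluded from inference rather than forced into a
category.

## Counting rule

Link **frequency counts articles, not statements**: a link may only be
extracted once per intervention description, so duplicated statements
within an article are collapsed before counting
(`deduplicate_links()`), keeping the most explicit record (highest
`explicitness`, then highest `empirical_status`). The frequency table
(`link_frequency_table()`) then counts, per (BCT, MoA) cell, the number
of distinct articles describing that link, with row marginals $m_B$,
column marginals $m_M$ and total $N$; by construction
$\sum_B m_B = \sum_M m_M = N$ on any scope.

Two scopes are implemented. The default, `categorized`, drops
`OTHER`/`UNRESOLVED` statements from the cells *and* the marginals and
$N$, because the enrichment tests are only meaningful over the 26
categories. The `all` scope retains them (as pseudo-categories) for
descriptive totals. The corpus the generator emulates does not report
the exact categorized-only $N$ used in its published tests, nor whether
its null marginals were computed before or after exclusion; both scopes
are therefore available, the printed p-values are not treated as exactly
recomputable, and no acceptance check asserts them.

## The enrichment test

For a cell with observed article count $k$, the null probability is the
marginal product
$$p_0 = \frac{m_B}{N}\cdot\frac{m_M}{N},$$
i.e. techniques and mechanisms are paired independently at their
observed usage rates, and the evidence of over-description is the exact
binomial upper tail
$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(N, p_0),$$
computed through the survival function (`pbinom(k - 1, N, p0,
lower.tail = FALSE)`), which avoids the catastrophic cancellation a
naive $1 - \mathrm{CDF}$ suffers at large $N$; the test suite checks it
against an independent direct-summation oracle to $10^{-12}$
exhaustively up to $N = 60$. The tail is one-sided because the question
is which links are agreed upon, not which are absent. Cells with $k = 0$
are not tested — absence of a described link is reported separately, not
assigned a p-value.

The significance criterion is raw $p < .05$ with **no multiple-testing
correction**, deliberately mirroring the synthesis convention this
pipeline reimplements, which treats the threshold as an arbitrary
minimum criterion for flagging relatively frequent links rather than as
family-wise inference. A Benjamini–Hochberg option
(`test_links(..., adjust = "BH")`) is provided as a clearly separate
extension. Display follows the censored convention: values below .001
print as `<.001`, otherwise three decimals. Reported means are rounded
half-up to two decimals and coverages to whole percent, matching the
printed convention (ordinary banker's rounding would turn 87/24 = 3.625
into 3.62 rather than the printed 3.63).

A caution for interpreting the raw criterion: testing only the cells
with $k \ge 1$ conditions on an outcome that is itself unlikely for rare
category pairs, so among *tested* cells with very small expected counts
the fraction flagged at $\alpha$ can exceed $\alpha$. The calibration
property below is therefore stated — as the analysis intends — for
designs in which every null expected cell count is at least 5.

## The heat map

`build_p_matrix()` arranges the tested cells as a BCT × MoA matrix of
p-values with `NA` for never-described links, optionally transformed to
$-\log_{10} p$ clamped at $10^{-16}$ (so the transform is bounded at
16). Rows and columns are clustered independently with agglomerative
hierarchical clustering, Euclidean distance on $-\log_{10} p$ (untested
cells imputed as $p = 1$) and average linkage. The source convention
specifies clustering but neither metric nor linkage; this pair was
chosen because the log scale lets strong links dominate the distances
while the clamp bounds their leverage, and both are arguments of
`cluster_orders()`. Agglomeration is deterministic on a given platform;
the guaranteed-deterministic artifacts are the ordered-matrix CSV and
the orders/merge-tree JSON, while raster bytes may vary with the font
stack. In rendered figures darker cells mean smaller p, and untested
cells are drawn in a sentinel colour distinct from the weakest tested
shade.

## The synthetic-corpus generator

`simulate_corpus()` is first-class, tested code: it generates corpora
with the statistical structure the analysis assumes, so every stage —
and the test's operating characteristics — can be exercised without any
external download. Its defaults are the emulation targets of the corpus
the pipeline was built around:

* **277 articles**; links per article follow a **zero-truncated negative
  binomial calibrated so the truncated distribution has mean 9.56 and SD
  13.80** (`sd > mean`: strong overdispersion; the truncation reflects
  the inclusion rule that every article describes at least one link).
  The underlying (size, mu) pair is solved numerically at call time —
  naively truncating an NB with mean 9.56 would push the realized mean
  to about 12.3.
* Flags: 33% of statements need inference, 12% are one-to-one, 0.9% are
  empirically tested. The share of mechanisms measured-but-not-tested is
  not reported anywhere; it defaults to 5%, a documented illustrative
  constant, as is the 5% default rate of uncategorizable (`OTHER`)
  labels.
* Usage weights over the 93 codes and 26 ids are Zipf-like ($w_r = 1/r$)
  because the real corpus is heavily concentrated (one mechanism
  absorbed more than a quarter of all links); for mechanisms the mass is
  ordered to put *Beliefs about Capabilities* first and *Intention*
  second. No per-category marginal table is published, so these weights
  are illustrative defaults, not estimates.
* Within an article, cells are drawn **without replacement** with
  probability proportional to
  `bct_weights × moa_weights × propensity`, mirroring the
  once-per-article extraction rule. `propensity` is an all-ones matrix
  under independence; cells with multiplier > 1 are recorded as planted
  ground truth (`plant_links()`, `recovery_metrics()`).
* A single integer seed drives one root generator; the global RNG state
  is restored afterwards.

What the generator does **not** emulate: coder disagreement and its
resolution, article screening, text ambiguity, correlation between flags
and link identity, and any real dependence structure between articles.
Passing calibration and power suites therefore demonstrates the
statistical machinery under the stated design, not coding accuracy on
real literature.

## Calibration and power study design

Both operating-characteristic suites run on reduced uniform grids, a
deliberate design choice: at the full 93 × 26 scale a corpus of ~2,600
links leaves expected cell counts far below 1, outside the stated
preconditions of both properties (expected counts ≥ 5 and ≥ 10
respectively).

* **Calibration** — 6 BCTs × 4 MoAs, uniform weights, 120 articles
  averaging 5 links: every null expected cell count is about
  600/24 = 25. Over 200 seeded replicates the mean fraction of tested
  cells flagged at $\alpha = .05$ must not exceed $3\alpha$; observed
  rates are far lower (the within-article without-replacement draw
  underdisperses counts, making the binomial reference conservative).
* **Power** — 10 BCTs × 6 MoAs, 400 articles averaging 5 links, one
  cell planted at twice its marginal product (null expected count about
  40 ≥ 10); sensitivity over 200 seeded replicates must reach 0.8. The
  larger grid matters: on a small grid an average of 5 links over 24
  cells saturates the planted cell (it can appear at most once per
  article), compressing the effective enrichment below its nominal 2×.

```{r calibration-example, eval = FALSE}
grid <- list(codes = bct_registry()$code[1:6], ids = as.character(1:4))
sim <- simulate_corpus(
  n_articles = 120, mean_links = 5, sd_links = 4,
  bct_weights = setNames(rep(1, 6), grid$codes),
  moa_weights = setNames(rep(1, 4), grid$ids),
  other_rate = 0, seed = 1)
mean(test_links(sim$corpus)$results$significant)
```

## Numerical and degenerate-input choices

* `expected_link_probability()` refuses $N \le 0$ and marginals outside
  $[0, N]$; a saturated corpus ($m_B = m_M = N$) gives $p_0 = 1$ and a
  single-link corpus is its own certain event ($p = 1$, never flagged).
* Dedup tie-break: explicitness, then empirical status, then first
  occurrence — deterministic for any input order; test results are
  invariant to statement order.
* Empty corpora yield empty-but-typed results everywhere (no division
  by zero): `corpus_summary()` returns `NA` moments,
  `summarize_significant()` a zero-summary row, `test_links()` an empty
  result set.
* The mean links per article divides by articles contributing ≥ 1 link;
  with the inclusion rule these are all articles. The emulated corpus
  reports a mean (9.56) that is not exactly its total over its article
  count (2,636/277 ≈ 9.52); the package documents its own denominator
  rather than guessing which was used.
* Censored display strings (`"<.001"`, `"<.050"`) are retained verbatim
  in the shipped tables and parsed as their bound with a censoring flag.

## Known limitations

* The shipped significant-link tables are a transcription of printed
  summaries; the underlying per-cell marginals are not public, so the
  printed p-values can be validated for internal consistency (both
  groupings carry the same 87 links) but not recomputed.
* The synonym seed is intentionally minimal; corpora with rich free-text
  labels will route many statements to `OTHER` until the user extends
  the map.
* The clustering layout of the published figure used an unspecified
  algorithm and is not reproducible verbatim; only this package's own
  clustering choices are deterministic surfaces.
* With `adjust = "none"` the flagged set is a descriptive ranking, not
  an error-controlled discovery set; at 93 × 26 scale several dozen
  false flags at $\alpha = .05$ are expected among hundreds of tested
  cells.
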