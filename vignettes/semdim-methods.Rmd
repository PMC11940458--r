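---
title: "Norming semantic dimensions and quantifying exclusivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming semantic dimensions and quantifying exclusivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdim)
```

## The problem

Dimension-rating studies ask raters to judge, on Likert scales, how relevant a
set of experiential dimensions is to a word's meaning. For abstract
vocabulary, the dimensions of interest here are introspective (INTRO), mental
state (MENT_ST), quantitative (QUANT), spatial (SPACE), social (SOC), moral
(MOR), theoretical (THEOR) and economic (ECO) content, collected alongside
classical psycholinguistic norms (concreteness, imageability, familiarity,
age of acquisition, semantic diversity) and affective norms (valence,
arousal). The central question is how *unidimensional* each concept is: is
its meaning dominated by one kind of experience, or spread over many?

`semdim` implements the full analysis path from raw rater-level records to:

1. two-stage quality control (careless-rater exclusion, then response-level
   trimming),
2. inter-rater reliability per variable (Cronbach's alpha),
3. word-level norms (mean, SD, n per word and variable),
4. the per-word **exclusivity** statistic and its low/medium/high
   stratification,
5. representative-dimension label sets, exact-combination intersection
   tables, and a dimension co-occurrence network with a two-cluster
   partition,

plus a synthetic rating generator that reproduces the statistical structure
the analysis assumes, so every stage is testable without access to collected
data.

## The exclusivity statistic

For a word with dimension means $m_1, \dots, m_8$ (each on the 1–7 scale),

$$E = \frac{\max_d m_d - \min_d m_d}{\sum_d m_d} \times 100 .$$

A word rated equally on all eight dimensions scores $E = 0$ (fully
multidimensional). The maximum on a 1–7 scale with eight dimensions is
$(7-1)/(7 + 7\cdot 1)\times 100 = 42.857$, attained by one dimension at 7
and the remaining seven at 1. $E$ deliberately mixes *how many* dimensions
characterise a word with *how strongly* they do: a word representative of a
single dimension still has low $E$ if that dimension's mean is modest,
because the denominator shrinks slowly while the range does all the work.

$E$ is computed from trimmed per-word means (not per-rater $E$ averaged),
is permutation-invariant in the dimensions, and is undefined for concrete
filler items, which lack meaningful dimension profiles.

Words are stratified at the 25th and 75th percentiles of the $E$
distribution: `low` ($E < p_{25}$), `medium` ($p_{25} \le E \le p_{75}$,
closed on both sides), `high` ($E > p_{75}$). Because percentile conventions
differ across software, `assign_levels()` exposes two: `"linear"`
interpolation between order statistics (R's default, type 7) and the
`"spss"` weighted-average convention (type 6). The two can differ in the
second decimal; `reproduce()` reports both so a published cutoff pair can be
attributed to its convention.

## Quality control

**Careless raters.** A rater is excluded when one response value accounts
for *strictly more than* 85% of their Likert responses, pooled across all
Likert-scaled variables. Age-of-acquisition responses are excluded from the
count: ages are open-ended numbers, not scale points, so a constant age
pattern is not evidence of careless responding on the Likert task. Whether
the 9-point affective scales should pool with the 7-point scales is not
settled usage; pooling everything Likert is this package's reading of "all
ratings", and the threshold is configurable.

**Response trimming.** Within each word × variable cell, responses farther
than 3 sample standard deviations (n−1 denominator) from the cell mean are
removed in a single pass. The candidate response is included in its own
cell's mean and SD by default; a `leave_one_out` flag switches to
leave-one-out statistics. Trimming applies to all 15 variables, ages
included. A second pass could remove more (trimming is not idempotent); the
pipeline never applies one.

Two numerical consequences are worth knowing. First, with include-self
statistics, two extreme responses in the same cell inflate the cell SD and
can *mask* each other: in simulations with 25-response cells and 1% planted
contamination, roughly a fifth of planted outliers share a cell with another
and aggregate recall drops to ~89%, while isolated planted outliers are
caught at over 99% (leave-one-out recovers ~98% overall). Second, detection
depends on the noise level: with rater noise of 1 scale unit, a response at
the scale extreme of a mid-scale item is often *within* 3 SD and is
legitimately kept. The package's tests therefore measure sensitivity in the
diagnostic regime (sparse contamination, noise SD 0.5) and document the
masking behaviour separately rather than pretending the single-pass rule has
uniform sensitivity.

## Reliability

Cronbach's alpha is computed per variable with raters as the scale "items"
and words as cases — the norming-study convention for inter-rater
consistency:

$$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right),$$

with $k$ raters, $s_i^2$ the variance of rater $i$ across words and $s_T^2$
the variance of per-word sums. The formula needs a complete word × rater
block, which a list design only provides within one list, so alpha is
computed per list and pooled as the unweighted mean across lists. This
pooling is a design choice: disjoint word lists admit no single complete
matrix, and published reports rarely state their handling. Raters with
missing responses on a list (e.g. after trimming) are dropped from that
list's block; lists reduced below 2 raters or 2 words are skipped with a
warning. Pooled alpha above 0.6 (exclusive) is flagged acceptable.

## Classification and the co-occurrence network

A word is **representative** of a dimension when its mean exceeds 3.5
(strict), the midpoint between the scale's neutral point and the first
clearly-related response. Comparisons use exact means by default; a
`round_norms_before_threshold` toggle reproduces analyses that thresholded
published 2-decimal norms, which can flip borderline words.

The exact-combination intersection table (the tabulation behind an UpSet
plot) partitions the representative words; words above threshold on no
dimension are excluded from it but reported separately. Two conservation
identities are enforced by tests: combination counts sum to the number of
representative words, and each dimension's marginal equals the sum of counts
of combinations containing it.

The bipartite word–dimension graph is projected onto the dimensions with
shared-word counts and Jaccard indices. The two-cluster structure is
extracted by average-linkage hierarchical clustering on $1 - \mathrm{Jaccard}$,
chosen as the simplest deterministic method whose output is comparable with
a qualitative two-cluster description; the linkage is configurable, and
dimensions are ordered lexicographically before clustering so ties resolve
deterministically. Force-directed layouts are cosmetic and out of scope; the
optional plots use deterministic layouts (a heatmap ordered by cluster).

## The synthetic generator

`make_profiles()` + `simulate_ratings()` emulate a list-based norming study:

* **Design defaults**: 964 items of which 157 concrete fillers, 24 lists
  dealt round-robin, 20 raters per list, every rater rating all 15 variables
  for their list's words. Each synthetic rater rates one list (real
  participants often rate two); because lists are disjoint and the rater
  offset is per rater, every downstream statistic is invariant to this
  simplification.
* **Relevance structure**: each abstract item draws $k \in 1..8$ relevant
  dimensions with weights `c(0.091, 0.19, 0.25, 0.28, 0.12, 0.05, 0.014,
  0.005)` — about 9% single-dimension words and a mode at 3–4 dimensions,
  echoing the cardinality pattern typical of abstract vocabulary. Relevant
  dimensions get true means uniform on (4.5, 6.8], irrelevant ones on
  [1.2, 3.2].
* **Response model**: `clamp(round(true_mean + rater_offset + noise),
  scale_min, scale_max)`, with half-away-from-zero rounding (any fixed
  convention works; this one is parity-free), rater offsets
  $N(0, \mathrm{noise\_sd}/2)$ and response noise
  $N(0, \mathrm{noise\_sd})$. The default noise SD of 1 scale unit puts
  pooled alphas in the 0.85–0.99 band, the range typical of published
  norming studies. Ages get uniform noise of ±2 years per unit of noise SD
  and are only bounded below.
* **Semantic diversity**: the latent SEM_DIV of abstract items is a
  linear-Gaussian function of standardised $-E$, calibrated so the
  population correlation equals `semdiv_coupling` (default −0.47), then
  mapped to the 1–7 scale around midpoint 4 with SD 0.8 (clamping is rare
  enough not to attenuate the correlation measurably). This is the simplest
  mechanism reproducing a negative E–SEM_DIV association for validity
  testing; it makes no claim about the causal structure of real semantic
  diversity.
* **Contamination**: `inject_careless()` replaces a configured fraction of
  raters with constant responders; `inject_outliers()` pushes a configured
  fraction of responses to the scale extreme opposite their item mean. Both
  return the planted ground truth so recovery tests can score exact
  flagging.
* **Planted cluster structure**: `dimension_families` restricts each item's
  relevant dimensions to one family, creating a block co-occurrence
  structure for testing cluster recovery.

Two discretisation effects matter for recovery claims. Rounding means a
noiseless simulation reproduces the *rounded* latent profile exactly, so
exact-recovery tests round the latent dimension means to integer scale
points first (recomputing the latent $E$); for continuous latents the
recovery error from discretisation alone is small but nonzero. Clamping at
the scale ends biases observed cell means of near-boundary items toward the
interior, which is why the generator's mean-recovery test conditions on
interior cells (true mean in [2, 6]).

What the generator does **not** emulate: real lexical co-occurrence
structure between dimensions (by default dimensions are drawn independently,
so the co-occurrence network of default synthetic data has no "true" cluster
structure), word frequency and length effects, rater demographics, realistic
age-of-acquisition response behaviour, and any contamination process beyond
constant responders and single-response extremes. Passing tests on
synthetic data therefore validate the *pipeline's arithmetic and
bookkeeping*, not claims about real ratings.

## Problem sizes and tolerances in the test suite

The suite runs at deliberately scaled sizes: the exclusivity property sweep
uses $10^5$ random profiles; QC recovery fixtures use 1000 items × 25
raters; E-recovery under unit noise uses 2000 items × 25 raters (mean
absolute error below 1.5 E-units); the SEM_DIV coupling is checked across 20
seeds of 807 items (within ±0.07 of −0.47); cluster recovery across 20
seeded 300-item runs. Oracle agreements (exclusivity, alpha, correlations)
are asserted to 1e-12; file round-trips to 1e-6 (norms are written with six
decimals).

## Reproduction mode

`reproduce()` runs every word-level stage on an externally supplied norms
table (with a `column_map` for foreign column names) and prints the computed
quantities next to the published reference values of the Italian
abstract-concept norming database this package targets
(`reference_values()`): percentile cutoffs 15.24 / 20.29, $E$ range
5.52–35.76, level counts 202/404/201, $r(E, \mathrm{SEM\_DIV}) = -0.47$,
per-dimension representative counts, and the
{INTRO, MENT_ST, SOC, MOR} vs {QUANT, SPACE, THEOR, ECO} cluster split.
Two caveats ship with those reference numbers: the published medium-level
lower bound appears both as 15.24 (cutoff) and 15.27 (smallest observed
medium value), and the mental-state representative count appears both as
420 and 419; `semdim` reports its computed values and leaves such source
discrepancies unadjudicated.

## Known limitations

* Alpha pooling across lists is unweighted; lists with more raters carry no
  extra weight. With near-balanced designs this is immaterial, but heavily
  unbalanced designs may warrant a rater-weighted pool.
* The single-pass 3-SD rule has the masking behaviour described above; it is
  kept because it is the standard norming-study rule, with leave-one-out as
  the documented alternative.
* The two-cluster partition is a deterministic description of the Jaccard
  structure, not an inferential claim; no significance testing of cluster
  structure is attempted.
* Exclusivity's upper bound depends on the scale and the number of
  dimensions; $E$ values are not comparable across studies using different
  dimension sets without renormalisation.
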