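---
title: "Methods and design of layercourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of layercourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layercourse)
```

## The data model

A layered network replicates one set of entities across layers, each
layer one type of biological measurement; every entity present on a
layer carries a vector of values over a shared grid of `N` time points,
with missing measurements preserved as `NA` (never coerced to zero — a
zero is a measured value with its own colour, grey). Time points are
ordered labels with an implied uniform spacing; we deliberately do not
require timestamps, because the experiments this design targets mix
units freely (days in one study, half-hours in another), and none of the
analyses below uses the spacing, only the order.

The on-disk form is a sectioned TSV (`#LAYERS`, `#TIMEPOINTS`,
`#VALUES`, `#EDGES`) with `NA` as the missing-value token, plus an
equivalent JSON object. The `#TIMEPOINTS` section is optional and
defaults to `t1..tN`. Values are written with 17 significant digits in
both dialects so that reading a written file reproduces the network
exactly, bit for bit; the test suite asserts this round trip. Entities
absent from a layer simply have no value row for it: layers may hold
different measurement sets.

## Colour encoding

Within one layer, values map linearly onto the segment between two
endpoint colours over that layer's `(minValue, maxValue)` — the extremes
of all non-missing values of the layer across the whole time course.
The mapping is per layer by construction: measurements on different
layers are generally in incomparable units, so a shared scale would
invite cross-layer readings that the data cannot support.

Three decisions here were genuinely open:

* **Orientation.** Both conventions (yellow = low and yellow = high) are
  in active use, so neither is treated as canonical: the default runs
  yellow at the layer minimum to blue at the maximum, and a `reversed`
  flag swaps them. Reversing the gradient and negating the values
  commute, which the tests check.
* **Grey at zero.** Grey marks *absolute* zero (|value| < 1e-12) and
  missing values, even when 0 lies strictly inside `(min, max)`. The
  alternative — grey only when 0 is an endpoint — would make a
  penetrance of exactly zero (phenotype absent) visually continuous with
  small positive penetrance, which is the distinction the grey is there
  to draw.
* **Degenerate layers.** A constant layer (`min == max`) has no gradient
  direction; every value takes the low-endpoint colour rather than
  erroring, since constant layers legitimately occur (e.g. an all-zero
  rare phenotype).

A value outside `[min, max]` by more than a small tolerance is an error:
it means the caller is colouring against stale layer statistics.
Similarity bins (below) use a separate white→red ramp, linear in the bin
index 0..10.

## Per-time-point clustering by distance geometry

At a single time point the per-entity values on one layer are scalars,
so the minimal faithful metric between entities is
`D[i][j] = |v_i(t) − v_j(t)|`; entities missing a value at `t` are
excluded and listed. The placement is distance geometry realised as
classical multidimensional scaling: square the distances, double-centre
(`B = −½ J D² J`), take the top three eigenpairs of `B`, and scale the
eigenvectors by the square roots of their eigenvalues. One-dimensional
metrics embed exactly in three dimensions, so for this use the
embedding reproduces `|v_i − v_j|` to numerical precision — the tests
assert recovery rather than coordinates, because coordinates are unique
only up to a rigid transform.

Numerical choices:

* **Negative eigenvalues** (a non-Euclidean input matrix, possible when
  a caller supplies an arbitrary metric) are truncated to zero, giving
  the best rank-3 approximation instead of an error.
* **Determinism.** Eigenpairs are sorted by eigenvalue descending and
  each axis's sign is fixed so that its largest-magnitude loading is
  positive. With this convention repeated runs produce byte-identical
  coordinates, which the snapshot draw manifest relies on.
* **Small n.** `n ≤ 3` configurations are padded with zero axes; a
  single point sits at the origin; an all-zero distance matrix puts all
  points at the origin.

`top_changers()` reports the entities with the largest
`|v(t+1) − v(t)|` on a layer. Ties at the k-th delta are all included
(the report may exceed `k`) — truncating ties would make the result
depend on entity declaration order. The default `k = 1` highlights one
entity per layer; it is a flag, not a model constant.

## Correlation significance

All unordered entity pairs within a layer are tested on their
time-series vectors, after pairwise-complete deletion of time points
missing in either series; the post-deletion count `n` is recorded in the
result, pairs with `n < 3` are skipped and counted, and constant series
are skipped (their correlation is undefined — deliberately not reported
as zero). Tests are two-sided throughout.

* **Pearson.** A pair is significant at level α when `|r|` reaches the
  critical value of the product-moment coefficient at `df = n − 2`,
  computed by exact inversion of the t test for a correlation,
  `r_crit = t_crit / √(t_crit² + df)`, rather than from a printed
  table. At `n = 3` (one degree of freedom) and α = 0.05 this yields
  0.9969…, i.e. the 0.997 threshold quoted for three-point series; the
  acceptance suite pins this value and the Monte-Carlo type-I error of
  the rule on Gaussian noise at n ∈ {3, 10, 50}.
* **Spearman.** The coefficient is the Pearson correlation of average
  ranks (ties averaged, no further tie correction), and significance
  uses `t = r√(n−2)/√(1−r²)` against a Student-t with `n − 2` df;
  `|r| = 1` maps to p = 0 by convention. The two routes are mutually
  consistent: r just below the Pearson critical value has p just above
  α under the t formula, and conversely — a property test covers the
  grid.

Offered levels are restricted to 0.10, 0.05, 0.02, 0.01 by default;
`allow_any_alpha` (CLI `--alpha-free`) unlocks arbitrary levels for
users who know why they want them. No multiple-testing correction is
applied by default — the correlations are meant as a first screen, and
silently reranking them would hide that — but a Benjamini–Hochberg
option exists for the Spearman p-values.

A pair is **recurrent** when significant on at least `min_layers ≥ 2`
layers. Per-layer signs are kept: a pair can be positively correlated on
one measurement level and negatively on another, and that pattern is
itself informative, so `consistent_sign` flags rather than filters it.
The `positive`/`negative` filters are strict — a pair with any
opposite-sign record among its counted layers is dropped — because a
user asking for "only positive recurrences" is asking about the pair,
not about individual records.

An important caveat travels with all of this: successive time points of
one series are not independent samples, so these significance rules are
rough indications of co-movement, not calibrated hypothesis tests. The
package implements the simple rules faithfully and does not attempt a
dependence-aware correction.

## Similarity scoring

Two schemes score an entity's whole vector on one layer:

* **Average** — the mean of the non-missing values.
* **Wilson lower bound** — each non-missing time point becomes a
  Bernoulli rating (positive iff strictly greater than
  `positive_threshold`), and the score is the lower endpoint of the
  Wilson score interval for the positive fraction at level α (default
  0.05, `z = 1.96`). The lower endpoint (the "−" branch of the ±) is
  what makes it a conservative ranking score: it is ≤ p̂ always, 0
  exactly when nothing is positive, and → p̂ as n grows.

How a continuous value becomes a "rating" is a convention this package
had to choose: the default threshold 0 counts strictly positive values,
which is the natural reading for non-negative penetrance scores (any
nonzero value = phenotype observed). It is a flag because other data
need other thresholds. A known behaviour follows directly: on a layer
where most values are small but nonzero, p̂ ≈ 1 for almost every entity
and Wilson bins saturate high — the test suite reproduces this on a
rare-phenotype-shaped layer. The scheme finds true signal *within* a
layer; it must not be used to compare layers.

Raw scores are binned per layer:
`bin = floor(10 · (raw − min)/(max − min))` clamped to 0..10, floor for
determinism at edges, degenerate range → all bin 0. Equal raw scores get
equal bins, and binning preserves ranking. Bins are per layer for the
same reason colours are.

## The synthetic generator

The generator exists so that every analysis above can be tested against
known ground truth. It draws a flat baseline per (layer, entity),
overlays planted structures, adds i.i.d. Gaussian noise, and clips at 0
on penetrance-style layers. Planted structures are exactly the patterns
the analyses target:

* **Correlated pairs** share a linear latent ramp over `signal_range`
  (mirrored for negative sign) plus independent noise. The noise level
  is tuned so the realised sample correlation exceeds the critical value
  at the spec'd number of time points: on the 3-point preset, where the
  critical value is 0.997, the preset noise (sd 0.07 against a ramp of
  spread 6) keeps planted pairs recoverable as recurrent in ≥ 95% of
  seeds, which the acceptance suite measures over 100 seeds.
* **Step changes** of magnitude `m` at index `i` shift the trajectory
  from `i + 1` on. To be recoverable as the top changer, `m` must exceed
  the largest per-interval ramp change, `Δ = span/(N−1)`; the presets
  use m = 5 against Δ = 3.
* **Latent late-onset signals** sit at the signal floor until an onset
  index, then ramp to the ceiling — the pattern of a knockdown whose
  phenotype emerges only late in the time course.
* **Rare-layer sparsity** zeroes a fixed fraction (preset: 0.8) of the
  non-planted entities on designated layers, noise-free, emulating a
  phenotype most knockdowns never show. The zeroed set is chosen
  deterministically (first eligible entities), so planted truths are
  identical across seeds; only baselines and noise vary.

Two presets fix the study shapes: `esc_core` (4 measurement layers —
histone acetylation, Pol II binding, mRNA, protein — 15 core stem-cell
genes, 3 time points at days 1/3/5, values on an arbitrary abundance
scale 1–9) and `mitotic_screen` (7 cell-division phenotypes, 1067 genes,
90 half-hour time points spanning 45 h, non-negative penetrance values
in [0, ~1], rare `grape` layer, a late-onset grape signal for one
tracked gene). Both can be scaled down (`n_entities`,
`n_time_points`), and onsets scale proportionally; the test suite runs
the mitotic shape at 20–60 genes and the recovery studies at 100 seeds
of the full `esc_core` preset, sizes chosen to exercise every planted
structure while keeping the default suite quick to run.

What the generator does *not* emulate: temporal autocorrelation of the
noise (noise is i.i.d. by design, matching the normality assumption of
the Pearson rule), realistic phenotype co-occurrence structure,
measurement-batch effects, and the actual values of any published
dataset. Passing recovery tests therefore shows the analyses are
correct and calibrated under the stated model — not that real screens
meet that model.

## Rendering

Snapshots are 2D small multiples, one panel per layer, replacing an
interactive stacked-3D scene: the analytic outputs (positions, colours,
sizes, markers), not a projection, are the contract. Node positions come
from the per-time-point embedding (first two axes) or from a fixed grid
shared across layers, so an entity keeps one position everywhere;
correlation edges are drawn yellow (positive) or red (negative); tracked
entities double in size; top changers get a star marker on every panel.
`render_snapshot()` returns a draw manifest (layer, entity, x, y, size,
colour, flags) that is byte-identical across runs — no jitter anywhere —
and the tests compare manifests, never pixels. A `--sweep` emits one
numbered image per time point; video assembly is left to external tools.

## Command-line interface

Eight subcommands (`convert`, `cluster`, `changes`, `correlate`,
`score`, `track`, `simulate`, `snapshot`) wrap the package functions;
`simulate` writes the TSV dialect to stdout so pipelines like
`simulate … | correlate --all-layers --recurrent` work. Alpha is
restricted to the four offered levels unless `--alpha-free` is given —
fidelity by default, flexibility on demand. Exit codes: 0 success, 1
validation/runtime error, 2 unknown subcommand.

## Known limitations

* The significance rules ignore serial dependence within a series (see
  above); results are screening indications.
* The distance-geometry literature contains several algorithm variants;
  this package commits to classical MDS, and its guarantee is distance
  recovery, not coordinate agreement with any other implementation.
* Wilson scoring's rating threshold is a convention; for data that are
  not penetrance-like the default (0) may be meaningless and must be
  set.
* Binning to 11 bins loses resolution by design ("similarly scoring
  entities colour identically"); use `raw_score` for any downstream
  arithmetic.
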