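# layercourse

Analysis of multi-layer, time-resolved biological networks in R.

Many genotype–phenotype experiments produce the same set of entities
(genes, proteins, knockdown targets) measured on several *layers* of
biology at once — e.g. histone acetylation, RNA polymerase II binding,
mRNA abundance and protein level after perturbing a stem-cell regulator;
or the penetrance of seven cell-division phenotypes over 90 time points of
a genome-wide RNAi screen. `layercourse` is for analysts of such data: it
treats the experiment as a layered network in which every entity carries
one time-series vector per layer, and provides the per-layer analytics
that make dynamic patterns visible and testable.

## What it computes

* **Per-layer colour encoding** — values map linearly onto a yellow→blue
  gradient over each layer's own `(minValue, maxValue)` range, with grey
  for absolute zero or missing values; a colourblind-safe blue–orange
  preset and a reversed orientation are available. Colours are never
  comparable across layers.
* **Per-time-point clustering by distance geometry** — for each layer and
  time point, the pairwise distance matrix `D[i][j] = |v_i(t) − v_j(t)|`
  is embedded in 3D by classical multidimensional scaling
  (`B = −½ J D² J`, top-3 eigenpairs, coordinates `V √λ`), placing
  entities with similar values close together without choosing a cluster
  count.
* **Top changers** — the entities with the largest `|Δvalue|` between
  consecutive time points, with ties included.
* **Correlation significance** — all pairwise time-series correlations per
  layer. Pearson significance uses the exact PMCC critical value
  `r_crit = t_crit / √(t_crit² + df)` with `df = n − 2` (no lookup table);
  for three time points this gives the familiar 0.997 threshold at
  α = 0.05. Spearman significance uses `t = r√(n−2)/√(1−r²)` against a
  Student-t with `n − 2` df. Offered levels: 0.10, 0.05, 0.02, 0.01.
  **Recurrent correlations** are pairs significant on ≥ 2 layers, with
  per-layer signs retained (mixed-sign recurrence is reported, not
  suppressed).
* **Similarity scoring** — per entity and layer, either (a) the mean of
  the value vector or (b) the lower bound of the Wilson score confidence
  interval for the fraction of "positive" time points,

  ```
  ( p̂ + z²/2n − z √( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n ),
  ```

  binned to 0–10 per layer and coloured white→red.
* **Synthetic data** — a seeded generator with planted correlated pairs,
  step changes, late-onset latent signals and rare-layer sparsity, plus
  presets matching the two study shapes above (4 layers × 3 days;
  7 phenotypes × 90 time points × 1067 genes).
* **Snapshots** — static small-multiple figures per time point (one panel
  per layer) with correlation edges, tracked entities and top-changer
  markers, plus a deterministic draw manifest for testing.

## Worked example

```r
library(layercourse)

net <- generate_network(synth_preset("esc_core", seed = 1))
net
#> layered_network: 4 layer(s), 15 entities, 3 time points
#>   layers: HIS, POL, RNA, PRO
#>   edges: 104 intra-layer, 0 inter-layer

pearson_critical_r(3, 0.05)
#> [1] 0.9969173        # |r| needed for p < 0.05 with 3 time points (df = 1)

recurrent_correlations(net, alpha = 0.05, min_layers = 2)
#>   entity_a entity_b n_layers      layers                      signs consistent_sign
#> 1    sall4    ewsr1        3 POL,RNA,PRO negative,negative,negative            TRUE
#> 2    sall4      yy1        2     RNA,PRO          positive,positive            TRUE
#> 3     sox2   zfp281        2     HIS,PRO          positive,negative           FALSE
#> 4    wdr18   zfp219        2     HIS,RNA          positive,negative           FALSE
#> 5      yy1    ewsr1        3 HIS,RNA,PRO positive,negative,negative           FALSE
```

The generator planted `yy1–ewsr1` and `sall4–ewsr1` as negatively
correlated on the mRNA and protein layers and `wdr18–zfp219` as positive
on acetylation but negative on mRNA; all three come back recurrent (the
extra rows are the induced `sall4–yy1` correlation and, at α = 0.05 with
only three time points, an occasional chance recurrence such as
`sox2–zfp281`). The entity with the largest change between days 1 and 3
on the acetylation layer is the planted step change:

```r
top_changers(net, "HIS", "day1", k = 1)
#> change report: layer 'HIS', day1 -> day3
#>   entity    delta
#> 1  prmt1 4.891485

wilson_lower_bound(c(rep(1, 5), rep(0, 5)))   # p̂ = 0.5, n = 10
#> [1] 0.2365931
```

A command-line interface wraps the same functions
(`inst/cli/layercourse`): `simulate`, `convert`, `cluster`, `changes`,
`correlate`, `score`, `track`, `snapshot`; see
`vignette source in vignettes/layercourse-methods.Rmd` for the model
details.

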