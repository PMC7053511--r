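# herdnet

Activity-stratified proximity networks for grazing herds.

`herdnet` turns focal-sampling observations of a herd — one activity
(grazing, moving, standing, ruminating, wallowing, lying, drinking) and one
set of proximity partners per animal per half-hour period — into an ensemble
of binary undirected social networks, one per (activity, period) over the
fixed full-herd vertex set, and asks two questions a behavioural ecologist
would ask:

1. **Do the animals structure their society differently by activity?**
   Answered by correlating each activity indicator with global network
   indices (density *D* = Σαᵢⱼ/(N²−N), number of connected components,
   clustering coefficient CC = N⁻¹ Σ CCᵢ) and with vertex centralities
   (degree, closeness Clᵢ = 1/Σⱼdᵢⱼ, Freeman betweenness
   bᵢ = Σ g_{j(i)k}/g_{jk}, and Perron–Frobenius eigenvector centrality).
2. **Do age and gender shape an individual's position?** Answered by
   Spearman rank correlations of age and gender (female = 1, male = 2)
   with the centralities, within each activity.

All indices are computed from first principles on the adjacency matrices
(and are tested against brute-force oracles and igraph); correlations are
Spearman midrank correlations with two-tailed t-based p-values, flagged at
p < 0.05 / p < 0.01. Because typical field data of this kind are not
public, the package includes a seeded synthetic-herd generator that emulates
the observation design (91 animals: 88 females aged 0.5–23 y targeting a
9-y mean, 3 males aged 2.5–3 y; 240 periods = 12 months × 2 days ×
10 half-hour steps) with per-activity social profiles: group size, group
closure (clustering), hub attachment (star-like structure), and age/gender
participation biases.

## Worked example

```r
library(herdnet)

res <- run_pipeline(generator_config(seed = 1))
#> simulated roster: 91 animals
#> simulated records: 21840 rows over 240 periods
#> built 1680 proximity networks (7 activities x 240 periods)
#> computed indices: 1680 networks, 152880 local cases
#> associations: 21 global, 28 local, 56 attribute results

res$correlograms$global
#>     variable density n_components clustering
#> 1    grazing  0.61**      -0.61**     0.66**
#> 2     moving  0.33**      -0.30**     0.32**
#> 3   standing  0.20**      -0.15**     0.16**
#> 4 ruminating   -0.03         0.00    -0.13**
#> 5  wallowing -0.39**       0.40**    -0.31**
#> 6      lying -0.13**       0.08**    -0.35**
#> 7   drinking -0.58**       0.58**    -0.35**
```

Reading the table: each cell is the Spearman rho between "this network is a
grazing (…) network" and the index, over all 1680 networks; `**` marks
p < 0.01. Grazing networks are denser, less fragmented and more clustered
than the rest of the ensemble; the rare resting activities (wallowing,
lying, drinking) show the mirror image, driven largely by their many empty
or near-empty networks. Individual results are retrieved with

```r
association_of(res, "age", "degree", activity_context = "moving")
#>   variable  index activity_context     n        rho             p significance
#> 9      age degree           moving 21840 -0.1925399 2.042132e-181       p<0.01
```

i.e. with the default generator's negative age bias on moving, older
animals hold fewer proximity partners while the herd moves.

## The analysis workflow

The `analysis/` scripts run the same pipeline as numbered steps, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1      # roster.csv, records.csv, manifest.json
Rscript analysis/02_build_networks.R  # ensemble counts; densest network per activity (GraphML)
Rscript analysis/03_indices.R         # indices_global.csv, indices_local.csv
Rscript analysis/04_associations.R    # associations_*.csv, correlogram_*.{csv,txt}
```

Large intermediates (records, index tables, GraphML files) are regenerated
by the scripts rather than stored.

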