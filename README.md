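# hifnet

Structural analysis of signaling-pathway networks in R: from a KEGG KGML
document (or a Pajek/TSV network snapshot) to topology indicators, directed
centrality tables, cohesive-subgroup and core extraction, bow-tie
macrostructure, and a scale-free (power-law) analysis of the degree
distribution with a bootstrap goodness-of-fit test.

The package was built around the hypoxia response: the HIF-1
(hypoxia-inducible factor 1) signaling pathway, whose KEGG map yields a
directed, unweighted network of ortholog groups, compounds, linked pathway
maps and complexes joined by activation / expression / inhibition relations.
It is equally applicable to any pathway network in the supported formats. Its
intended users are systems-biology and network-medicine analysts who want the
classical Pajek-style indicator set as scripted, tested, reproducible code.

## What it computes

* **Graph construction** — `parse_kgml()`, `read_pajek()`, `read_edge_tsv()`
  build a typed `pathway_graph` (one arc per ordered pair, first-declared
  class wins; self-loops allowed). `write_pajek()` / `write_edge_tsv()` go
  the other way.
* **Topology** — `summarize_topology()`: node/line counts, density with and
  without self-loops (m/n² and m/(n(n−1))), average degree 2m/n, directed
  diameter and mean geodesic distance over reachable pairs.
* **Centrality** — degree (DC = Din + Dout), closeness
  CC = (N−1)/Σ d (with a reachability-scaled convention on disconnected
  graphs and a strict mode), betweenness
  BC = 2·Σ g_jk(i)/g_jk / ((N−1)(N−2)), plus `top_k()` ranked tables.
* **Subgroups** — `weak_components()`, `component_table()`,
  `extract_largest()` for the core subnetwork.
* **Bow-tie** — `bowtie_partition()` over
  {LSCC, IN, OUT, TUBE, TENDRIL, DISCONNECTED} (metabolic aliases GSC/S/P/IS),
  with singleton cores supported and degenerate ones flagged.
* **Scale-free analysis** — `fit_powerlaw()` fits Pr[X ≥ x] ~ x^(−a) by the
  continuous-approximation MLE
  â = 1 + n[Σ ln(x_i/(x_min − ½))]⁻¹, selects x_min by minimizing the
  Kolmogorov–Smirnov distance L, and tests the fit with a semi-parametric
  bootstrap p-value (p ≤ 0.1 flags rejection). An exact zeta-normalized
  discrete MLE is available via `exact = TRUE`.
* **Orchestration** — `run_pipeline()` runs all stages and writes the
  TSV/JSON report bundle; `inst/scripts/hifnet-cli.R` is a thin command-line
  front end. Synthetic generators (`make_bowtie_graph()`,
  `make_kgml_fixture()`, `make_random_digraph()`, `sample_powerlaw()`)
  produce test inputs with exact ground truth, and
  `synthetic_hif_network()` ships a deterministic synthetic snapshot
  reproducing the published aggregate structure of the HIF-1 pathway network.

## Worked example

```r
library(hifnet)

g <- synthetic_hif_network()
summarize_topology(g)
#> Topology summary
#>   nodes: 85   lines: 61
#>   density: 0.00844291 (loops) / 0.00854342 (no loops)
#>   average degree: 1.43529412
#>   diameter: 5   mean distance: 1.83051
#>   node kinds: ortholog 59, compound 16, map 8, group 2, undefined 0
#>   arc classes: activation 29, expression 26, inhibition 6, other 0

core <- extract_largest(g)
bowtie_partition(core)
#> Bow-tie partition
#>   LSCC         (GSC): 1
#>   IN           (S): 20
#>   TENDRIL     : 13

fit <- fit_powerlaw(attr(degree_distribution(core), "sample"),
                    n_boot = 1000, seed = 42)
fit
#> Power-law (Pareto tail) fit, discrete half-shift convention
#>   alpha = 2.92, xmin = 2 (tail n = 20 of 34)
#>   KS distance L = 0.0467
#>   bootstrap p = 0.6450 (1000 datasets): consistent with a power law
```

Reading the output: the 85-node network splits into 25 weak components; its
34-node, 34-line core is a bow-tie with a one-node strongly connected hub,
a 20-node input fan and 13 tendril nodes and no output fan. The core's degree
tail above x_min = 2 is consistent with a power law (the bootstrap p-value is
far above the 0.1 rejection threshold); the scale parameter is 2.92 under the
continuous-approximation estimator and 3.28 under the exact discrete MLE
(`fit_alpha(deg, 2, exact = TRUE)`).

The same run from a shell:

```sh
Rscript inst/scripts/hifnet-cli.R run --input network.net --format pajek \
        --out results/ --nboot 1000 --seed 42
```

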