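# ppienrich

Network enrichment analysis of gene modules on protein–protein interaction
(PPI) scaffolds.

## The problem

Expression experiments produce gene lists of very different pedigree:
curated functional categories (GO-like terms, pathway collections),
co-expression modules found by biclustering, and differential-expression
signatures. Whether such a list represents a genuine functional unit should
leave a topological footprint: mapped onto a scaffold interactome, a real
module induces a subnetwork that is better connected than equally sized
random node sets. `ppienrich` is for anyone who wants to score that
footprint — per module, and comparatively across whole collections of
modules.

## The method

A list is mapped onto the scaffold and its **minimal connected network**
(MCN) is built: the induced subgraph over mapped members, optionally
extended by **external linker nodes** (non-list proteins adjacent to at
least two list members, compensating incomplete lists). Four parameters are
measured within the MCN:

- connection degree `k(v)`;
- clustering coefficient `C(v) = e_n / (n_v (n_v − 1) / 2)`;
- relative betweenness `rC_B(v) = C_B(v) / ((n − 1)(n − 2)/2)` with
  `C_B(v) = Σ_{s≠t≠v} σ_st(v)/σ_st` over shortest paths;
- the number of connected components.

The random expectation at list size `N` comes from resampling: `N` nodes
drawn uniformly from the scaffold, the MCN rebuilt the same way, `R` times
(default 1000). Node-level values are pooled and compared by a one-sided
two-sample Kolmogorov–Smirnov test (`D⁺ = sup_x [F_null − F_obs]`,
`p = exp(−2 m D⁺²)`); the component count is tested against the empirical
lower tail with an add-one correction. Collection drivers aggregate
percent-significant tables, stratify by module attributes (namespace,
direction, …) or term-DAG level, compare pooled parameter distributions
between classes (two-tailed KS), and cross-classify network significance
against conventional Fisher-exact term over-representation.

## Worked example

Everything below is generated in code — no downloads. Simulate a benchmark
with known ground truth (5 planted functional modules, 5 random signatures,
1 module split in two halves that only an external hub reconnects), then
analyze it:

```r
library(ppienrich)

dir <- file.path(tempdir(), "demo")
run_simulate(synth_spec(n_nodes = 500, mean_degree = 4, module_size = 15,
                        n_modules_per_class = 5, n_linker = 1, seed = 42), dir)

scaffold <- read_interactome(file.path(dir, "scaffold.tsv"))
#> PPI scaffold interactome: 500 nodes, 1141 edges (non-filtered)

modules <- read_gmt(file.path(dir, "modules.gmt"))
analyze_module(modules[["T:func01"]], scaffold, allow_external = TRUE,
               reps = 1000, seed = 1)
#> Network enrichment of module 'T:func01' [modules]
#>   15 mapped members (0 unmapped), external nodes allowed, R = 1000
#>   degree       p = 2.212e-06 *
#>   clustering   p = 5.565e-08 *
#>   betweenness  p = 4.241e-05 *
#>   components   p = 0.003996 *
#>   (* significant at alpha = 0.05)
```

All four parameters of the planted module sit far beyond the resampling
null: its nodes have more interactions, denser neighbourhoods, stronger
hub structure and fewer disconnected pieces than random 15-gene lists on
this scaffold. At the collection level the planted classes separate
cleanly:

```r
set <- analyze_collection(modules, scaffold, reps = 1000, seed = 1)
summary(set, stratify_by = "class")
#>   collection    stratum n_analyzed n_skipped pct_degree pct_betweenness
#> 1    modules functional          5         0        100             100
#> 2    modules     linker          1         0        100               0
#> 3    modules  signature          5         0         20              20
#>   pct_clustering pct_components
#> 1            100            100
#> 2            100            100
#> 3             20              0
```

Planted cohesive modules are flagged essentially always, uniform random
lists near the nominal rate. `run_analyze()` / `run_compare()` wrap the
same pipeline with TSV/JSON output, and
`Rscript inst/cli/ppienrich.R analyze --scaffold ... --modules ... --out ...`
exposes it from the shell.

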