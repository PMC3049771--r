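---
title: "Network enrichment of gene modules on a PPI scaffold: methods and design"
author: "ppienrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment of gene modules on a PPI scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppienrich)
```

## The question the method answers

A gene list -- an expression signature, a co-expression module, a curated
functional category -- implicitly claims that its members act together. If
that is true, the proteins they encode should interact more than arbitrary
proteins do: mapped onto a scaffold interactome, the list should induce a
subnetwork that is better connected than random lists of the same size.
`ppienrich` quantifies that claim. It builds the **minimal connected
network** (MCN) a list induces on the scaffold and asks, for four
topological parameters, whether the observed values lie beyond what random
node sets produce.

## The model and its pieces

**Scaffold.** An undirected simple graph; each edge may carry evidence
category tags. Two flavours are supported: the *non-filtered* scaffold with
every reported interaction, and the *filtered* scaffold keeping only edges
supported by at least two distinct evidence categories. Self-interactions
are discarded at load time: every statistic below assumes a simple graph.

**MCN.** The *base* MCN is the subgraph of the scaffold induced by the
mapped list members; members with no surviving edge stay as singleton
components (dropping them would silently inflate connectivity). The
*extended* MCN additionally admits **external linker nodes**: scaffold
nodes outside the list that are adjacent to at least two distinct mapped
members. The rationale is that real lists are incomplete -- a protein that
escaped detection may be exactly the one holding a module together -- so
one non-list node is allowed wherever it bridges two list members.
Admission is per node and deterministic: no path search imports arbitrary
intermediates, which keeps the construction reproducible and the null model
exactly parallel.

**Parameters.** For a node $v$ with $n_v$ neighbours and $e_n$ edges among
those neighbours, within the MCN:

* connection degree $k(v)$ -- the number of incident edges;
* clustering coefficient $C(v) = e_n / \binom{n_v}{2}$, set to 0 when
  $n_v < 2$;
* relative betweenness $rC_B(v) = C_B(v) / \binom{n-1}{2}$ where
  $C_B(v) = \sum_{s \ne t \ne v} \sigma_{st}(v) / \sigma_{st}$ sums over
  unordered pairs the fraction of shortest paths through $v$ (unit edge
  weights, per connected component), and $n$ is the total number of MCN
  nodes; defined as 0 when $n < 3$;
* the number of connected components, singletons included.

The normalization of $rC_B$ by $\binom{n-1}{2}$ with $n$ the whole MCN size
(not the component size) is the standard undirected convention; it keeps
$rC_B \in [0,1]$ with equality only for the centre of a star that spans the
MCN.

**Null model.** The random expectation at list size $N$ is built by
resampling: draw $N$ nodes uniformly without replacement from the scaffold,
rebuild the MCN *with the same external-node mode as the observed
analysis*, record all node-level parameter values and the component count,
and repeat $R$ times. Node-level values from all repetitions are pooled
into one reference distribution per parameter. $N$ is the *mapped* member
count, so observed and null networks are size-matched after mapping losses.
Uniform (not degree-matched) sampling is the default, which is the literal
reading of sampling "from the reference interactome"; a degree-matched mode
exists for sensitivity analysis.

**Tests.** Degree, clustering and relative betweenness use a one-sided
two-sample Kolmogorov-Smirnov test with alternative "observed greater":
$D^+ = \sup_x\,[F_{\mathrm{null}}(x) - F_{\mathrm{obs}}(x)]$ and the
asymptotic $p = \exp(-2 m (D^+)^2)$ with
$m = n_1 n_2/(n_1 + n_2)$, clipped to $(0,1]$. Component counts use the
empirical lower tail with an add-one correction,
$p = (1 + \#\{c_{\mathrm{null}} \le c_{\mathrm{obs}}\})/(R+1)$, which can
never return 0. No multiple-testing correction is applied across the four
parameters or across modules: results are reported as raw $p$-values with
significance flags at a configurable $\alpha$, and a Benjamini-Hochberg
step is available downstream where term over-representation is involved.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `reps` (R) | 1000 | null repetitions; pooled node-level samples grow as ~R·N, so 1000 already gives tens of thousands of reference values. Raise to 10000 for publication-grade tails. |
| `alpha` | 0.05 | significance level for flags and summaries. |
| `allow_external` | `TRUE` | the extended-MCN analysis; incomplete lists (signatures) benefit most. Must match between observed and null sides, which the driver enforces. |
| `size_min`, `size_max` | 3, 200 | mapped-size window; below 3 members no meaningful topology exists, above 200 the resampling null becomes expensive and undiscriminating, so such modules are skipped with an explicit reason. |
| `min_evidence` | 0 | 0 = non-filtered scaffold; 2 = the filtered, at-least-two-evidence-categories scaffold. |
| `seed` | -- | every sampler is bit-reproducible from its seed; reruns with equal configuration give byte-identical output files. |

## The synthetic benchmark

Because the interactome releases behind any given study age quickly, the
package ships generators that emulate the *statistical structure* the
pipeline consumes rather than any particular database snapshot:

* **scaffold** -- preferential attachment (heavy-tailed, like real
  interactomes) or Erdős–Rényi, with evidence tags assigned so a
  configurable fraction survives the filtered path;
* **functional modules** -- planted node sets whose induced density is
  raised to a target (default 0.3), the cohesive, module-like class;
* **signatures** -- uniform random lists, the unstructured class;
* **linker modules** -- two cliques joined only through one non-member
  hub, the fixture for the external-node rescue (the construction isolates
  the chosen nodes first, so the hub is provably the only bridge);
* a small GO-like DAG annotating each functional module, so propagation,
  over-representation and the ORA-vs-network classification can be tested
  with known truth.

What passing tests on these benchmarks *do not* show: real scaffolds have
far higher triangle density and evidence structure than the generators;
identifier mapping losses, literature bias toward well-studied proteins and
correlated annotation errors are not emulated. Results on synthetic data
validate the machinery and its calibration, not biological conclusions.

## Numerical choices and degenerate inputs

* KS $p$-values use the asymptotic one-sided formula throughout; observed
  samples are compared against pooled nulls that are large by construction,
  where the asymptotic form is accurate. $D^+$ is evaluated over the
  combined sample points, which is exact for step ECDFs.
* Ties are ubiquitous (degrees are small integers; clustering is mostly 0
  in sparse networks). Ties make the one-sided KS conservative. For the
  clustering coefficient on sparse scaffolds this is extreme: random MCNs
  contain almost no triangles, the pooled null is nearly degenerate at 0,
  and the test essentially cannot reject at nominal rates -- its observed
  type-I rate sits far below $\alpha$. Clustering significance should
  therefore be read as a very conservative call at low scaffold densities
  (the acceptance script measures the realised rate).
* Betweenness and clustering of nodes in graphs below their defining sizes
  ($n < 3$, $n_v < 2$) are 0 by convention, never `NaN`.
* Modules that map to fewer than `size_min` or more than `size_max`
  members are skipped with `skipped_reason = "size out of range"`; modules
  with no mapped member at all with `"no members in scaffold"`.
* An empty scaffold after evidence filtering is an error, not an empty
  result.
* Null distributions are cached keyed on (scaffold digest, $N$, external
  mode, $R$, seed, sampling mode); equal-size modules share one null
  bit-identically.

## Design decisions that were genuinely open

* **MCN = induced subgraph.** "Connecting" a list via shortest paths could
  be read as Steiner-like path inclusion; that would make the construction
  solver-dependent and non-deterministic. The induced subgraph (plus the
  single-linker extension) is deterministic, and since the null uses the
  identical construction the test is internally consistent.
* **Pooled two-sample KS.** Repetition-level node values are pooled into
  one reference multiset rather than, say, averaging per-repetition ECDFs;
  pooling is the simplest scheme that yields a proper reference sample at
  every list size.
* **External nodes count as observations.** Linker nodes are MCN nodes, so
  their parameter values enter the observed distributions; the null's
  linkers enter symmetrically.
* **GO level = shortest path to the namespace root**, computed by BFS over
  parent links; it is the common deterministic convention.
* **Net-significance for the ORA cross-classification** means "any of the
  four parameters significant", matching the permissive reading of a
  module having "some" significant network parameter.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run, as the package's own chosen
study conditions: oracle equivalence on 200 random graphs of up to 30
nodes; calibration with 500 uniform lists of $N = 20$ against a 2000-node
preferential-attachment scaffold of mean degree 4 at $R = 1000$; power on
100 planted modules (size 20, internal density 0.3) embedded in one such
scaffold and sharing one cached null; class separation on a 20 + 20
functional/signature benchmark. The linker-rescue and size-filter checks
are deterministic.

## Known limitations

* The extended MCN admits single linkers only; chains of two or more
  non-list nodes are never imported.
* Uniform null sampling ignores the degree bias of study effort in real
  interactomes; the degree-matched option mitigates but does not remove
  this.
* The clustering-coefficient test is severely conservative on sparse
  scaffolds (see above).
* Edge weights, directions and interaction signs are out of scope; every
  graph is treated as simple and undirected.
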