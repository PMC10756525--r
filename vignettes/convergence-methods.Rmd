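---
title: "Methods: testing convergence of heterogeneous circulating miRNA signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing convergence of heterogeneous circulating miRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRConverge)
```

## The problem

Case-control studies of circulating microRNAs in the same disease routinely
report almost disjoint lists of differentially expressed miRNAs. One
resolution is that the disagreement is superficial: different miRNA
combinations can regulate the same genes, so heterogeneous signatures may
still *converge* on a common, functionally interconnected set of targets.
miRConverge implements a complete, testable pipeline for that hypothesis:
per-gene targeting-frequency scores, a permutation null for convergence and
interconnectivity, curation of a directed activating gene network with
Katz-centrality-weighted final gene scores, and a per-miRNA
path-attenuation influence score.

## The scoring model

The aggregated signature is a set of miRNAs, each labelled **high**
(elevated in cases) or **low** (decreased), with study provenance. A miRNA
reported in both directions by different studies is rejected as an input
error — the aggregation model has no way to resolve such a conflict, and
silently dropping or averaging it would bias the score.

Given a miRNA–target interaction table reduced to unique (miRNA, gene)
pairs — evidence multiplicity is deliberately ignored, so each distinct
miRNA casts one vote per gene — every gene receives

$$\mathrm{score}(g) = \#\{\text{high miRNAs targeting } g\} -
  \#\{\text{low miRNAs targeting } g\}.$$

Genes targeted by no signature miRNA are omitted rather than scored zero,
so the score table enumerates only the targeted universe. Identifiers are
compared case-insensitively after trimming; `-5p`/`-3p` arms are distinct
miRNAs; gene symbols are taken as printed with no alias resolution.

## Permutation null

Convergence is assessed by resampling: `nIter` random signatures with the
same high/low composition as the observed one are drawn uniformly without
replacement from the interaction table's full miRNA universe (the observed
miRNAs are not excluded — the null is "an arbitrary signature of this
composition"). Each random signature is processed exactly like the
observed one, and two statistics are recorded:

* the **summed frequency score of the top k genes** (k = 100 by default),
  measuring convergence on a small target set; ties at the k-th rank are
  broken lexicographically by gene symbol, a fixed deterministic rule so
  the statistic is reproducible under a seed (the selection flags boundary
  ties so a user can see when a different rule could matter);
* the **number of PPI connections among those k genes** at each confidence
  threshold (0.4, 0.7, 0.9 by default), measuring functional
  interconnectivity. Each null set's edge count uses that set's own top-k
  genes.

Both empirical p-value conventions are reported: the *strict* convention
$p = r/N$ (null values strictly above the observed) and the *add-one*
convention $p = (r' + 1)/(N + 1)$ with $r'$ counting ties as exceedances.
The strict form mirrors the "r of N controls scored higher" arithmetic of
the published analysis; the add-one form is never exactly zero and is the
honest summary when no null value reaches the observed statistic. The
original analysis drew its randomness from a physical quantum source; a
seeded pseudo-random generator is used here instead, since reproducibility
matters to the tests and only the statistical behaviour of the draw, not
its physical provenance, affects the result.

## Directed network curation and final gene scores

A subset of most-impacted genes (frequency score ≥ 5 by default) is
selected, and a signed, partially directed functional-interaction network
over those genes is consumed as input. Curation proceeds in a fixed order:

1. **Trimming** — undirected edges are removed; bidirectional edges are
   split into two opposite directed edges.
2. **Cross-referencing** — the trimmed network is compared against the
   undirected PPI graph restricted to the same genes at threshold 0.95;
   pairs connected there but absent from the directed network (in either
   direction) are reported for manual resolution.
3. **Annotation** — a manual-review table resolves direction and sign of
   such pairs; resolved edges are added, never overwriting existing ones.
   A sign conflict on an existing ordered pair is a hard error.
   Inhibition edges discovered this way enter the network and are removed
   by the next step, which is outcome-equivalent to never adding them.
4. **Activating filter** — inhibiting edges and edges of uncertain sign
   are dropped, leaving high-confidence activating interactions only.

On the resulting graph, **Katz centrality** with the incoming-edge
convention is computed: $x_v = \beta + \alpha \sum_{u \to v} x_u$, with
$\alpha = 0.1$, $\beta = 1$. Because miRNAs lower protein abundance, the
most *downstream* nodes of the activating network of miRNA targets are the
most *inhibited* proteins, which is what incoming-edge Katz ranks. Three
numerical choices are deliberate:

* the system is solved **exactly** as $(I - \alpha A^\top)x = \beta 1$,
  not by truncated iteration;
* before solving, the convergence precondition
  $\alpha\,\rho(A) < 1$ (spectral radius) is verified and a violation is a
  hard error reporting $\rho$;
* scores are left **unnormalized** (a node with no incoming edges scores
  exactly $\beta = 1$), because the final ranking multiplies centrality by
  the frequency score and a unit-norm rescaling would destroy the
  interpretability of that product. Selected genes that are isolated in
  the activating network are retained with $x = \beta$, so every selected
  gene has a combined score.

The **combined score** is $\mathrm{katz}(g) \times \mathrm{score}(g)$,
the final per-gene impact measure.

## miRNA influence ranking

Each elevated miRNA is scored by using the activating network in reverse:

$$I_{\text{miRNA}} = \sum_{g} s_g \sum_{p} \alpha^{\,l_p},$$

summing over all *unique paths* $p$ from the miRNA (through its direct
targets) to each reachable gene $g$, with $l_p$ the path length in edges,
$\alpha = 0.1$, and $s_g$ the gene's final combined score (not its raw
frequency score — the "previously established final score").

Two interpretation decisions were genuinely open and are fixed as follows:

* **"Unique paths" means simple paths** (no repeated node). The activating
  network contains cycles, under which unrestricted walks are infinite;
  simple paths are the only finite reading.
* **Paths are capped at `maxPathLen = 8` edges** to bound enumeration. At
  $\alpha = 0.1$ a length-9 path contributes at most $10^{-9} \cdot s_g$,
  far below the two-decimal precision at which influence scores are
  reported; raising the cap by one changes any score by at most
  (number of new paths) $\times\ \alpha^{L+1} \times \max_g s_g$.
* Influence is computed for elevated miRNAs only, matching the framing
  that elevated miRNAs drive the suppression phenotype; decreased miRNAs
  can be scored by passing them explicitly. The influence graph is built
  on the activating-only network — the same graph the final scores come
  from; using the full signed network instead would mix attenuation signs
  and is not implemented.

## Synthetic data: what it emulates and what it does not

The generators produce the combinatorial structure the analysis consumes,
nothing more: a bipartite miRNA–gene targeting table, an undirected
confidence-scored PPI network, a signed partially directed network, and a
signature. A **planted convergent cluster** of `clusterSize` genes is
targeted by the signature-high miRNAs with probability `pCluster`
(background `pBackground`) and internally PPI-connected with probability
`qCluster` (background `qBackground`) — exactly the convergence-plus-
interconnectivity structure the statistics are designed to detect.
Setting `pCluster = pBackground` and `qCluster = qBackground` yields an
exchangeable null with no signal.

Default parameters are fixed once as the package's study conditions: a
signature of 37 high and 19 low miRNAs (the pooled published signature's
composition), a universe of 300 miRNAs × 1000 genes, `pBackground = 0.02`
(a realistic per-miRNA target fraction of ~20 recorded targets per miRNA
at this gene-universe size), and a strong planted effect
(`clusterSize = 60`, `pCluster = 0.35`, `qBackground = 0.005`,
`qCluster = 0.5`) for power checks. Cluster PPI confidences are drawn
from 0.9–1 so the planted interconnectivity survives stringent
thresholds; background confidences span 0.15–0.95. Targeting is
independent Bernoulli — the simplest exchangeable model consistent with
the uniform resampling null; degree-preserving nulls are out of scope.
The generators do not attempt realistic sequence features, expression
levels, fold changes, miRNA target-count heterogeneity, or PPI degree
distributions, so passing calibration and power checks demonstrates
correctness of the statistical machinery under exchangeability, not
performance on real databases with their strong ascertainment biases.

The directed-network generator needs two parameters beyond the planted-
cluster model: an edge density (`pDirectedEdge`) and a fraction of
unknown-sign edges (`unknownFraction`), so that trimming, annotation and
the activating filter are all exercised.

## Calibration and power checks

The test suite verifies, at sizes chosen to keep a full run in minutes on
one CPU:

* **Type-I calibration**: across 200 independent null datasets
  (150 miRNAs × 500 genes, `pBackground = pCluster = 0.03`, equal PPI
  probabilities and confidence ranges, 500 permutation replicates each),
  the fraction of datasets with add-one sum-statistic p ≤ 0.05 must fall
  inside the exact binomial 99% interval around 0.05.
* **Power**: at the default strong-effect configuration, the strict sum
  p-value is ≤ 0.01 in ≥ 90% of 50 seeded runs (200 replicates each).
* **Exactness**: on a universe small enough to enumerate every possible
  signature, the empirical p converges to the exhaustive-enumeration p
  within Monte-Carlo error; Katz solutions match the truncated walk
  series on 100 random graphs to 1e-9 and hand-solved closed forms to
  1e-12; influence scores match exhaustive simple-path enumeration on 100
  random graphs to 1e-12.
* **Determinism**: identical inputs and seed give byte-identical output
  trees.

## Degenerate inputs and edge policies

* PPI self-loops are dropped with a message (public PPI dumps contain
  them); duplicate undirected pairs keep the maximum confidence.
* Duplicate interaction records collapse to one pair; reading a
  concatenation of a file with itself gives the same table.
* Confidence normalization from the 0–1000 integer dialect is exact at
  the endpoints (0 → 0, 1000 → 1) and order-preserving; out-of-scale
  scores are a hard error, not clamped.
* An empty score table writes a header-only file; an empty network gives
  an all-$\beta$ centrality table.
* Evidence-strength ("support type") filtering of interaction records is
  not applied — all recorded interactions count.

## Known limitations

* The headline numbers of the original analysis (128 genes with score
  ≥ 5, sum-test p ≈ 0.0018, edge-test p ≲ 0.0001, the published influence
  values) depend on the real miRTarBase 2020, STRING and a hand-curated
  network, none of which ship with the package; they are documentation
  context, not recomputable targets. The packaged signature fixture does
  reproduce the pooled signature counts (56 / 37 / 19 / 4) exactly.
* The per-study split in the packaged fixture is a synthetic partition:
  the published table reports only pooled lists plus dual-study flags.
* Simple-path enumeration is exponential in the worst case; the default
  length cap keeps it tractable on curated sparse networks but dense
  graphs with hundreds of interconnected nodes may require a lower cap.
* No identifier normalization beyond case/whitespace: miRBase version
  aliases and gene-symbol aliases are the caller's responsibility.
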