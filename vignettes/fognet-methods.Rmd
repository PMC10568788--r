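---
title: "Methods: graph-based prediction of contractility regulators and image statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based prediction of contractility regulators and image statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fognet)
```

## The model

A protein–protein interactome is an undirected, unweighted simple graph
`G = (V, E)`: nodes are proteins on a canonical identifier space (FlyBase
FBgn for *Drosophila*), edges are experimentally observed interactions.
`fognet` builds `G` by merging per-database edge tables: identifiers are
mapped to the canonical space, edges are deduplicated as unordered pairs,
self-loops are discarded, and every merged edge retains the set of
`(source, citations, PSI-MI codes)` evidence entries supporting it. The
merge is associative and order-invariant, so adding a database never
requires rebuilding from scratch.

Prediction starts from a *positive set* `P ⊆ V` — proteins already known
to act in the pathway of interest — and asks which unlabeled nodes are
conspicuously close to `P`. Three complementary notions of "close" are
implemented; their disagreement is informative, which is why the package
reports per-method membership rather than a single merged score.

### Steiner tree approximation

A Steiner tree is a minimum-cost connected subgraph of `G` spanning all of
`P`; the non-positive nodes recruited by the tree are the candidates.
Exact Steiner is NP-hard, so `steiner_candidates()` uses the
metric-closure construction: complete graph on the terminals weighted by
pairwise shortest-path distance, minimum spanning tree of that closure
(Kruskal on a deterministic `(weight, endpoint, endpoint)` order), each
closure edge expanded to a concrete shortest path, a spanning tree of the
expansion, and iterative pruning of non-terminal leaves. On unit weights
this classic construction is within `2 (1 − 1/|P|) < 2×` of optimal.
`exact_steiner()` — a Dreyfus–Wagner dynamic program with full
backtracking — certifies optimality on small instances and anchors the
test suite's bound checks; it deliberately refuses instances beyond ~20
nodes / 6 terminals, where its exponential table stops being sensible.

### Paths to the target

For a pathway with a known convergence point (here Sqh, NMII's regulatory
light chain), `paths_to_target_candidates()` computes one shortest path
per positive to the target; interior path nodes are candidates. Among
equal-length paths the lexicographically smallest node sequence is chosen,
obtained by greedily stepping to the smallest-named neighbour that is one
BFS step closer to the target. This tie-break is arbitrary as biology but
essential as engineering: it makes candidate tables byte-reproducible. An
`"all"` mode unions every shortest path instead, for sensitivity analyses
— the single-path mode is a sample of the all-paths candidate set.

### Ranked paths

Each unlabeled node `v` receives `s(v) = Σ_{p ∈ P} 1 / d(v, p)` with
`1/∞ = 0`, so positives unreachable from `v` (or absent from the graph
entirely) contribute nothing rather than erroring. Scores are normalized
before thresholding. Two conventions exist for the normalizer: dividing by
the score total, or by the maximum. A fixed selection cutoff of 0.7 is
only meaningful under max-normalization — under sum-normalization at
interactome scale no node can reach 0.7 unless it dwarfs all others — so
max-normalization is the default and sum-normalization is kept as an
option. The selection rule is strict (`normalized > 0.7`); at
`threshold = 1` even the top node is excluded, which the tests pin down as
the boundary semantics.

## Combination and screening filters

`combine_methods()` reduces 1–3 method results to a per-protein membership
table with Venn counts; candidates found by several methods are the
natural follow-up priorities. `filter_candidates()` then annotates each
row with the first matching exclusion, in fixed priority order: already a
known pathway member, then a known interactor of the target, then not
expressed in the assay cell line (applied only when an expression list is
supplied). Priority order matters only for the reported *reason*; the
retained set is the same under any order.

## Image statistics

The validation assays are scored from 2-D grayscale intensity images with
a region-of-interest mask (drawn manually in practice; `segment_mask()`
reproduces the workflow automatically as Otsu threshold → largest
connected component → hole fill).

The **coalescence index** summarizes how organized a fluorescence signal
is: in-mask intensities are min–max normalized to `[0, 1]` and the index
is their mean divided by their sample (n−1) standard deviation.
Normalizing "to a scale of 0–1" is implemented per cell (min–max), the
only scale-free reading that lets cells from different images be compared;
a consequence, verified in the tests, is exact invariance to affine
intensity maps `v → a·v + b`, `a > 0`. The sample-SD convention is a
package decision (per-cell pixels are treated as a sample) and is what the
closed forms in the tests assume. An optional `"binary"` preprocess first
binarizes in-mask values at an Otsu level computed within the mask, after
which the index has the closed form `p / sqrt(p (1 − p) n / (n − 1))` for
above-threshold fraction `p`. Whether coalesced signal scores higher or
lower depends on this preprocessing choice — under `"binary"` the index
peaks at `p = 0.5` regardless of spatial arrangement — so the package
asserts only formula-level properties and leaves directionality to the
user's calibration on their own imagery.

Also provided: `intensity_ratio()` (quotient of integrated in-mask
intensities of two channels, e.g. phosphomyosin over actin),
`normalized_mean_intensity()` (per-cell intensities divided by the
brightest cell), and `contraction_fraction()` (contracted over contracted
plus relaxed per frame, ambiguous cells excluded from the denominator;
frames with no unambiguous cell report `NA`, never 0).

## Synthetic data: what it emulates, and what it does not

`generate_interactome()` produces an Erdős–Rényi background graph with a
planted answer: a target node, `n_positives` positives, and `n_planted`
"true candidates" each wired to `wiring_positives` distinct positives and
to the target. The defaults — 50 nodes, edge density 0.08, 8 positives, 4
planted, 3 wired positives each — were chosen once as a regime where the
planted nodes are favoured by all three algorithms simultaneously
(length-2 positive→target bridges, adjacency to several positives, cheap
tree connectors) yet the background is dense enough to offer genuine
decoys. Recovery at these settings was measured in a single pre-registered
run and then frozen into the tests. `generate_cell_image()` draws an
elliptical cell with a ring, punctate or diffuse signal plus truncated
Gaussian noise; a noiseless diffuse cell is intentionally the degenerate
(zero-spread) input for the coalescence index.

What passing on synthetic data shows: the algorithms are implemented
correctly (bounds, oracles, closed forms, determinism) and the pipeline
composes. What it does not show: performance on a real interactome, whose
heavy-tailed degree distribution, study bias and evidence noise the
Erdős–Rényi generator makes no attempt to match, nor anything about
real microscope optics. Published headline counts from the original
*Drosophila* analysis (an interactome of 11,473 proteins and 233,054
edges; 99 candidates, 4 found by all three methods) depend on archived
2017 database snapshots and on an unrecorded shortest-path tie-break, and
are therefore not asserted anywhere in the test suite.

## Numerical and engineering choices

- Unreachability is represented as `1/∞ = 0` in scores and as explicit
  `unreachable` / `dropped_terminals` reports in path and tree methods;
  disconnected graphs are never fatal unless no two terminals can be
  joined at all.
- All randomness flows from explicit integer seeds
  (`withr::with_seed`); no function touches global RNG state.
- Edge identity is the canonically ordered pair (`protein_a < protein_b`),
  making tables sortable and byte-stable across runs.
- Unmapped identifiers are kept as-is with a warning by default (merged
  public tables usually arrive pre-mapped); `"drop"` is opt-in.
- Test and acceptance problem sizes — 200 Steiner instances at 8–12
  nodes, 60–100 path/score graphs at 6–13 nodes, 20 recovery seeds —
  are the package's chosen trade-off between coverage of random structure
  and keeping the exact (exponential) oracles comfortable.

## Known limitations

- The interactome is unweighted; no confidence weighting of evidence.
- No diffusion/random-walk prioritisers; the three implemented methods
  define the framework's scope.
- Candidate sets carry no statistical significance — they are screening
  priorities, not hypothesis tests.
- Contracted/relaxed/ambiguous counts are manual inputs; the package does
  not classify cell morphology.
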