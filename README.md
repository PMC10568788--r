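# fognet

Network-based prioritisation of candidate regulators of non-muscle myosin
II (NMII) contractility, with the fluorescence statistics used to validate
them at the bench.

## The problem

Apical constriction — the cell-shape change driving gastrulation, neural
tube closure and wound healing — is powered by NMII, whose activation in
*Drosophila* runs through the Fog pathway (Fog → Mist/Smog → Concertina →
RhoGEF2 → Rho1 → Rok) and converges on phosphorylation of the regulatory
light chain Sqh. Genome-wide RNAi screens can find new members of such a
pathway but are slow and false-positive-prone. An alternative is to mine a
protein–protein interactome: pool the proteins already known to matter (the
*positives*), then ask which unlabeled proteins sit suspiciously close to
them in the interaction graph.

`fognet` implements that computational framework end to end:

1. **Interactome assembly** — merge per-database edge tables (TSV) into one
   undirected simple graph with per-edge provenance (sources, literature
   citations, PSI-MI evidence codes), after mapping every protein to a
   canonical FlyBase identifier and dropping self-loops.
2. **Three prediction algorithms** over the graph `G = (V, E)` with
   positive set `P ⊆ V`:
   - *Steiner tree approximation*: connect all of `P` with as few edges as
     possible; the non-positive connector nodes are candidates. The
     metric-closure construction guarantees a tree within 2× of the optimal
     Steiner tree; a Dreyfus–Wagner exact solver (`exact_steiner()`)
     certifies the bound on small instances.
   - *Paths to the target*: one shortest path from each positive to a
     target node (Sqh for this pathway); interior path nodes are candidates.
   - *Ranked paths*: each unlabeled node `v` scores
     `s(v) = Σ_{p ∈ P} 1 / d(v, p)` (reciprocal shortest-path distances,
     `1/∞ = 0`); after normalization, nodes scoring `> 0.7` are candidates.
3. **Combination and filtering** — per-protein method membership (Venn
   counts), then screening filters: drop known pathway members, known
   target interactors, and proteins not expressed in the assay cell line.
4. **Image statistics** for the validation assays: the coalescence index
   (mean / SD of min–max-normalized in-mask intensities — high for
   organized peri-nuclear NMII rings, low for dispersed signal), integrated
   intensity ratios (phosphomyosin:actin), normalized mean intensity, and
   contracted-cell fractions.
5. **Synthetic generators** — seeded random interactomes with a planted
   regulator module and synthetic punctate/diffuse/ring cell images, so the
   whole pipeline runs and is tested without any external download.

## Worked example

```r
library(fognet)

sim <- generate_interactome(seed = 42)   # 50-node graph, planted module
sim$interactome
#> <interactome> 48 proteins, 107 interactions from 1 source(s): synthetic

st <- steiner_candidates(sim$interactome, sim$positives)
pt <- paths_to_target_candidates(sim$interactome, sim$positives, sim$target)
rk <- ranked_candidates(ranked_paths_scores(sim$interactome, sim$positives))
tab <- combine_methods(list(st, pt, rk))

glance(tab)
#> # A tibble: 1 × 4
#>   n_candidates n_retained n_in_all_methods n_in_two_or_more
#>          <int>      <int>            <int>            <int>
#> 1            7          7                1                5

venn_counts(tab)
#> # A tibble: 4 × 2
#>   combination                              n
#>   <chr>                                <int>
#> 1 paths_to_target+ranked_paths             2
#> 2 paths_to_target+ranked_paths+steiner     1
#> 3 ranked_paths                             2
#> 4 ranked_paths+steiner                     2
```

Seven candidates were proposed in total; one (`P021`) was found by all
three methods — and it is one of the four planted true regulators
(`sim$planted_truth`), illustrating why candidates recovered by several
methods are prioritised for screening. On the imaging side:

```r
ring <- generate_cell_image(mode = "ring", seed = 42)
coalescence_index(ring$image, ring$mask, preprocess = "binary")
#> # A tibble: 1 × 3
#>      ci n_pixels preprocess
#>   <dbl>    <int> <chr>
#> 1 0.698     2284 binary
```

Real runs are driven by a YAML config through `run_pipeline()` (or the
thin CLI in `inst/cli/fognet.R`), which writes the merged interactome,
candidate table, method subgraphs and a summary JSON. Applied to a full
*Drosophila* interactome built from six interaction databases (FlyMine,
DroID, Mentha, MyProteinNet, SignaLink, FlyReactome) and 104 pooled
positives, this workflow is the one that surfaced the published candidate
regulators of Fog-driven contractility.

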