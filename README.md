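# exposnet

Growing semantic networks from expositional text: meso-scale structure
and topological knowledge gaps.

## What this package is for

A textbook (or any carefully ordered exposition) introduces concepts one
sentence at a time and relates them to concepts the reader already has.
`exposnet` turns a plaintext exposition into that growing network and
quantifies how it is built:

1. **Concept extraction.** Candidate keyphrases are chunked between stop
   words and scored with a frequency-penalized RAKE variant,

   `score(k) = score_RAKE(k) / (1 + ref(k))`, with
   `score_RAKE(k) = Σ_i deg(k_i) / freq(k_i)`,

   where `deg`/`freq` are keyword degree and frequency in the RAKE
   co-occurrence graph and `ref(k)` is the phrase's count in a reference
   corpus of ordinary prose — common phrases are demoted, technical ones
   survive. The top-ranked phrases form the *index set* of concepts.
2. **Network construction.** Concepts are nodes; two concepts are linked
   if they ever co-occur in a sentence, with integer weight equal to the
   number of co-occurring sentences (the *total network*). Recording the
   first sentence at which every node and edge appears yields the
   *expositional filtration* `G_1 ⊆ … ⊆ G_N` of binary graphs, one per
   sentence, plus a one-at-a-time (OAAT) refinement that adds a single
   element per step.
3. **Meso-scale structure.** A core–periphery partition maximizes the
   core-ness quality `Q_C = (1/v_C)(Σ_{i,j∈core}(w_ij − γw̄) −
   Σ_{i,j∈periphery}(w_ij − γw̄))`; periphery communities maximize the
   modularity `Q_M = (1/v_M) Σ_{i≠j}(w_ij − γ s_i s_j / v_M) δ(c_i,c_j)`
   with `v_M = 2m`. Introduction curves (fraction of a group introduced
   by normalized time `t`) and the signed area between the core and
   periphery curves quantify how early the core is built.
4. **Knowledge gaps.** Persistent homology (Z/2, dimensions 0–2) of the
   clique complexes `X(G_1) → … → X(G_N)` tracks topological cavities —
   disconnected components, unfilled loops, enclosed voids — as they are
   born and filled during exposition. Summaries: the barcode, Betti
   curves `β_n(t)`, interval counts `m_k`, and the normalized average
   cycle lifetime `D_k = (1/(m_k N)) Σ_i (d_i − b_i)` (with `d_i = N+1`
   for cavities that never fill).
5. **Null models.** Five seeded nulls calibrate every metric: random
   index (random non-stop words as concepts), random sentence order,
   continuous configuration (degree- and strength-preserving rewiring),
   random edge order, and node-ordered (each node arrives with all its
   back-edges) filtrations, with 100-instance ensembles by default.

A synthetic-document generator with planted core–periphery + community
structure (`latent_model()`, `generate_document()`) makes the whole
pipeline testable end to end without copyrighted texts.

## Worked example

```r
library(exposnet)
model <- latent_model(seed = 7L)      # 15 core + 45 periphery concepts
sp <- synth_pipeline(model)           # document -> tokens -> network
sp$doc
#> <tokenized_document 'synth-7': 1079 sentences, 7270 tokens (0 VAR, 0 #)>

cp <- coreness_partition(sp$network, restarts = 10, seed = 7)
cp
#> <core_periphery: 15 core, 45 periphery, Q_C = 0.4383 (gamma = 1)>
pm <- periphery_modularity(sp$network, cp, runs = 10, seed = 8)
pm
#> <community_partition: 5 communities, Q_M = 0.7013 (gamma = 1)>
```

The detected core is exactly the planted 15-concept core and the five
planted periphery communities are recovered. The core is introduced
earlier than the periphery:

```r
f <- sp$filtration
curve_area_difference(
  introduction_curves(f, intersect(cp$core,      names(f$node_birth))),
  introduction_curves(f, intersect(cp$periphery, names(f$node_birth))))
#> [1] 0.054       # positive: core precedes periphery
```

Knowledge gaps over the exposition, versus a random-edge-order null:

```r
bc <- persistent_homology(f)
bc
#> <barcode: N = 1079; m_0 = 11, m_1 = 73, m_2 = 40>
round(normalized_cycle_lifetime(bc)$D, 3)
#>   D_0   D_1   D_2
#> 0.107 0.150 0.084

ens <- build_ensemble("random_edge", list(g = filtration_graph(f)),
  metrics = list(m_1 = function(fr)
    interval_counts(persistent_homology(fr))[["m_1"]]),
  size = 20, master_seed = 99)
c(empirical = interval_counts(bc)[["m_1"]], null_mean = mean(ens$metrics$m_1))
#> empirical null_mean
#>      73.0      92.4
null_percentile(interval_counts(bc)[["m_1"]], ens$metrics$m_1)
#> [1] 0          # the exposition opens fewer loops than random edge order
```

So this synthetic exposition behaves like a well-ordered text: the core
arrives early, and random reorderings of the same relations open more
1-dimensional knowledge gaps than the exposition itself.

`plot_barcode(bc)`, `plot_betti_curves(betti_curves(bc))` and
`plot_introduction_curves()` draw the standard figures;
`analyze_document()` bundles the whole per-document analysis into one
summary, serialized deterministically by `summary_to_json()`.

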