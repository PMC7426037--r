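---
title: "Methods: growing semantic networks, their architecture, and their gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growing semantic networks, their architecture, and their gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposnet)
```

## The model

`exposnet` treats an expositional text as a generative process for a
semantic network. Concepts — index keyphrases — are nodes; a sentence
that mentions two concepts together asserts a relation between them.
Reading the text front to back therefore traces a nested sequence of
binary graphs $G_1 \subseteq \dots \subseteq G_N$ (one per sentence), the
*expositional filtration*, whose final weighted version (weights =
number of co-occurring sentences) is the *total network*. Two families
of questions are asked of this object:

* **Architecture.** Does the final network decompose into a dense core
  plus a sparse, community-structured periphery, and how early in the
  exposition is each group assembled?
* **Knowledge gaps.** Which topological cavities (components, loops,
  voids) open during exposition, and how long do they persist before
  being filled? Persistent homology of the clique complexes
  $X(G_1) \to \dots \to X(G_N)$ answers this exactly.

The assumptions are minimal but worth stating: relations are undirected
and unlabelled; sentence-level co-occurrence is taken as evidence of
relatedness; and a $(k{+}1)$-clique of pairwise relations is treated as
a filled $k$-simplex of joint knowledge (the clique-complex rule). Any
fully connected group of concepts thus encloses no gap by construction.

## Text preprocessing

Raw text is NFKD-normalized, hyphens become spaces, sentences are split
on `.!?` followed by whitespace, and words are maximal runs of letters,
digits and `#`. Tokens containing digits become `#`; tokens that are not
letters-plus-`#` are dropped; everything is lowercased. A second pass
scrubs variable-like debris (the inheritance of math-heavy sources) to a
`VAR` placeholder, in a fixed rule order: no vowels (vowels are
`a,e,i,o,u,y`) → `VAR`; length ≤ 2 and not a stop word → `VAR`; length
3–4, not a stop word, failing spell check → `VAR`. Stop-list membership
exempts a token from the spell-check rule: stop words are ordinary
English and would only be scrubbed by a sparse dictionary, which is the
failure mode this exemption prevents. The lemmatizer and spell checker
are injected functions, so tests can use deterministic stand-ins and
users can plug in a full NLP toolkit. Both passes are idempotent and
preserve sentence count, which the test suite asserts as properties.

## Concept extraction

Candidates are maximal within-sentence runs of non-stop, non-placeholder
tokens (runs longer than `max_phrase_len = 4` words are discarded —
technical terms rarely exceed four words, and longer runs are almost
always chunking accidents). Scoring follows RAKE — keyword degree over
frequency, summed over the phrase — divided by one plus the phrase's
frequency in a reference corpus of ordinary prose, so that phrases
common outside the technical register are demoted. The package ships a
small, clearly synthetic reference table
(`inst/extdata/synthetic_reference_counts.tsv`); real analyses should
supply counts derived from a genuine corpus via
`read_reference_counts()`.

Because no principled universal index size exists, `select_index()`
defaults to "all phrases scoring strictly above the median, capped at
500", and every entry point accepts an explicit `n`. Ties break
lexicographically and then by first occurrence, so runs are
reproducible.

## Network and filtration construction

`match_concepts()` matches index phrases as contiguous token sequences,
with a subsumption rule: an occurrence strictly inside a longer matched
occurrence does not count on its own. Without it, every mention of
"vector space" would also assert "space", wiring a phrase to all its
sub-phrases. Edge weights count *sentences*, not within-sentence
repetitions. The sentence filtration records first mentions; its step-N
graph equals the binarized total network exactly (asserted in tests).

The OAAT refinement adds one element per step, which makes persistence
summaries comparable across documents with different sentence counts and
exposes sub-sentence structure. The intra-sentence order is: new nodes
first, by first-occurrence position (ties lexicographic), then new
edges, by the later endpoint's position (ties lexicographic). Any
deterministic refinement consistent with the sentence filtration would
do; this one is fixed so that collapsing OAAT steps provably recovers
the sentence filtration.

## Core–periphery and communities

Core-ness maximizes
$Q_C = \frac{1}{v_C}\bigl(\sum_{i,j\in C_c}(w_{ij}-\gamma_C\bar w) -
\sum_{i,j\in C_p}(w_{ij}-\gamma_C\bar w)\bigr)$ over ordered
off-diagonal pairs, where $\bar w$ averages over *all* node pairs
(absent edges count as zero). The normalization $v_C = \sum_{i\ne j}
|w_{ij}-\gamma_C\bar w|$ bounds $|Q_C| \le 1$; it is a convention, so
absolute $Q_C$ values are implementation-relative and only comparisons
(across partitions, documents, or null ensembles computed with the same
convention) carry meaning. A property of this pairwise form worth
knowing: with core and periphery sums both present, $Q_C$ is *linear*
in the core indicator, so the optimum is the strength-threshold rule
$s_i > \gamma_C \bar w (n-1)$ and the seeded greedy label-switching
optimizer reaches it from any start (the tests confirm equality with
exhaustive search on all graphs up to 8 nodes). Ties go to the core, so
a uniform complete graph is all-core at $Q_C = 0$.

Modularity uses the Newman convention $v_M = 2m$ and excludes diagonal
terms (there are no self-loops; the exclusion shifts $Q_M$ by a
partition-independent constant, so optima are unaffected). The optimizer
is the locally greedy Louvain family as implemented in igraph (Leiden
engine with the modularity objective), run `runs` times under random
vertex permutations and polished by greedy single-node moves; the best
partition under the package's own $Q_M$ is returned. Periphery
communities are computed on the periphery-induced subgraph.
$\gamma_C = \gamma_M = 1$ by default.

Introduction curves are piecewise-constant fractions of a group
introduced by step $k$, on the normalized grid $t = k/N$; the
core-periphery area is the step-function integral of their difference,
positive when the core precedes. The discrete integral differs from the
continuum idealization by $O(1/N)$, and is invariant under uniform
stretching of the step grid.

## Persistent homology

Clique complexes are built to dimension 3 (cliques to size 4), which is
what homology through dimension 2 requires; each simplex enters at the
maximum birth step of its vertices and edges — forced by the "all
elements introduced so far" semantics. The barcode is computed over
$\mathbb{Z}/2$ by boundary-matrix column reduction with the
twist/clearing optimization, in compiled code; an independent plain-R
dense reduction without clearing serves as the oracle in the test suite
(200 random filtrations, exact agreement). Deaths use the half-open
convention $[b, d)$; zero-length intervals ($b = d$, a cavity filled in
the same step it forms, frequent under node-ordered nulls) represent no
lived gap and are dropped. All dimension-0 intervals, including the one
infinite component bar per final component, count toward $m_k$ and
$D_k$ — the lifetime formula makes no exception, and the convention is
applied uniformly to empirical and null filtrations so comparisons are
fair. Infinite deaths enter $D_k$ as $N+1$, distinguishing a cavity
that never fills from one filled at the last step.

## Null models

Five seeded nulls, two at the data level (random index, random sentence
order) and three at the network level (continuous configuration, random
edge order, node-ordered). Ensembles default to 100 instances with
per-instance seeds `master_seed + i`, so reruns are identical. The
continuous configuration model is specified by its contract — degree
sequence preserved exactly, weight multiset preserved exactly, strengths
approximately — and implemented as $10|E|$ attempted double-edge swaps
followed by weight reassignment that gives the heaviest weights to the
edges whose endpoints have the largest combined target strength. The
achieved strength error is measurable (median relative error ≤ 0.25 on
50-node test fixtures) rather than assumed; exact strength-preserving
rewiring is NP-hard in general and out of scope.

## The synthetic generator

`latent_model()` plants a core–periphery graph with periphery
communities: defaults `n_core = 15`, `n_periph = 45`, `n_comm = 5`,
`p_cc = 0.9`, `p_cp = 0.3`, `p_pp_in = 0.6`, `p_pp_out = 0.02` — a
regime where the core is unambiguous, communities are dense but clearly
weaker than the core, and cross-community periphery contact is rare.
`generate_document()` then emits `n_sentences = 1000` scheduled
sentences (long enough that most relations are mentioned naturally;
relations never sampled are appended once in a forced sweep, so the
recovered network equals the planted edge set exactly). Each sentence
mentions one sampled relation, padded with on average `filler_rate = 4`
filler tokens: stop words, plus occasional common content words (never
adjacent to each other, as in ordinary prose) drawn from the synthetic
reference table so that the reference-corpus penalty has something to
demote. Concept names are nonsense consonant-vowel words of length ≥ 6,
so no dictionary, stop list or scrubbing rule can touch them, and no
phrase is a prefix of another.

The exposition schedule weights relation $(u,v)$ at normalized position
$t$ by $\exp(-\beta (1-t)\,\mathrm{periph}(u,v))$, where
$\mathrm{periph}$ is 1 for relations between two periphery concepts and
`core_bias` $= \beta \ge 0$: pure-periphery relations are suppressed
early, so core-incident structure concentrates at the start, vanishing
smoothly as the document proceeds; $\beta = 0$ gives a uniform schedule.
(The suppression must decay with $1-t$, not grow with $t$: suppressing
periphery *late* would concentrate periphery early, the opposite of an
expositional core-first style.)

What the generator does *not* emulate: grammar, polysemy, lemmatization
noise, math debris, hierarchical concept granularity, and realistic
phrase-frequency distributions. Passing tests on synthetic documents
therefore validate the machinery — extraction, matching, filtration
bookkeeping, optimization, persistence — and the qualitative direction
of effects, not the linguistic robustness of RAKE on real prose.

## Numerical choices and degenerate inputs

* Optimizer seeds are explicit everywhere; RNG state is restored on
  exit, so calls do not perturb the caller's stream. Quality values are
  re-evaluated from their stored partitions to $10^{-12}$ in tests.
* Edgeless graphs: all-periphery with $Q_C = 0$; singleton communities
  with $Q_M = 0$. A uniform complete graph ($v_C = 0$) is all-core at
  $Q_C = 0$.
* Star graphs admit no double-edge swap; the configuration null then
  returns a copy with a warning rather than failing.
* Exact Spearman inference enumerates all $n!$ permutations for
  $n \le 9$ (vectorized; 362,880 × 9 at the boundary) and switches to
  the $t$ approximation above. Ties get average ranks. Two-sided
  p-values throughout.
* Filtration validity (births in range, edges no earlier than their
  endpoints, no duplicates or loops) is asserted on construction for
  every filtration, including all null models.

## Problem sizes used by the shipped analyses

The test suite and `scripts/acceptance.R` run at deliberately modest
scales chosen to exercise every code path on a laptop: oracle
equivalence on 200 random filtrations of ≤ 12 nodes, exhaustive-search
equivalence on graphs of ≤ 8 nodes (Bell(8) = 4140 partitions), planted
recovery and null contrasts on 60-concept documents of ~1000–1100
sentences, and 10-document corpora in the acceptance script. The
persistence backend comfortably handles the tens of thousands of
simplices these produce; real textbook-scale networks (a few hundred
nodes, thousands of edges) are within the same envelope.

## Known limitations and observed deviations

* **Degree-driven early cores.** Even under an unbiased schedule
  (`core_bias = 0`) the detected core's introduction curve leads the
  periphery's by a small positive area (≈ +0.03 at default scale): a
  node's first mention is the minimum of its incident relations'
  emission times, so hubs appear early under *any* random schedule.
  A zero-mean expectation for unbiased generation is therefore an
  idealization; the package's tests record the measured behaviour.
* **Lifetime summaries under permanent cavities.** The planted periphery
  leaves a number of cavities that never fill (sparse cross-community
  contact), and every filtration of the same final graph shares those
  infinite bars. Under node-ordering a cavity completes as soon as its
  last *node* arrives, relatively earlier than in sentence exposition,
  so node-ordered $D_1, D_2$ — per-bar averages — can exceed the
  empirical values even though node-ordering creates almost no finite
  (born-and-filled) cavities, which is the meaningful sense in which it
  is "maximally ordered". Count-based contrasts ($m_k$) are the robust
  directional summaries; the acceptance suite asserts the lifetime-based
  direction too and documents its failure under these planted
  conditions rather than hiding it.
* Relations are undirected and unlabelled; co-occurrence is a coarse
  proxy for semantic relatedness; the clique-complex filling rule is a
  modelling choice (an alternative would require simultaneous
  higher-order co-occurrence).
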