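---
title: "Detecting circular permutations with invariant structure embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular permutations with invariant structure embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two proteins are related by circular permutation (CP) when they share the
same global fold but their N and C termini sit at different sequence
positions — as if one chain had been circularized and re-cut elsewhere.
Structure search tools that embed a protein as a function of its residue
*order* systematically miss such pairs: the geometry is unchanged, but every
order-dependent feature moves. `cpscan` implements a complete, self-contained
pipeline for finding CP-related pairs:

1. **Representation** (`build_graph`): a protein is its Cα contact graph
   (10 Å cutoff) with three node features — normalized local density ρ,
   terminal indicator τ, and a 64-dimensional sinusoidal positional
   encoding s.
2. **synCP** (`syncp`): a *synthetic circular permutation* cyclically
   reorders the Cα sequence without moving an atom. For a chain of length n
   there are exactly n of them. Because edges and ρ depend only on
   distances, a synCP changes exactly τ and s — it isolates the
   order-dependence of any downstream score.
3. **Encoder** (`train`, `encode`): an E(3)-invariant message-passing
   network embeds each structure; supervised contrastive training pulls
   same-family structures together. When synCP augmentation is on, every
   sampled structure is replaced by a random synCP of itself, so the model
   is forced to score a structure and its permutants as the same protein.
4. **CP-aware alignment** (`align`, `align_cp`, `delta_cp`): a TM-score
   aligner plus the duplicate-and-align trick (concatenate the query with
   itself so the alignment can wrap). ΔCP = TM(cp) − TM(plain) is strictly
   positive exactly when allowing the wrap improved the alignment; a pair
   is called CP when TM(cp) > 0.5 and ΔCP > 0.
5. **Discovery** (`discover_cp`): two encoders — one trained *without*
   augmentation (CP-sensitive baseline) and one *with* it (CP-invariant) —
   score all pairs; pairs the baseline misses (cosine < 0.6) but the
   invariant model matches (cosine > 0.9), or with a score difference
   ≥ 0.7, are candidates, then verified by the aligner.

## The encoder in detail

Messages depend only on the incident node features and the squared
inter-node distance, never on raw coordinates, so every embedding is
*exactly* invariant to rigid motions — an architectural property that holds
with random weights. Invariance to circular permutation is *not*
architectural: it is learned from the augmentation, and the package's tests
assert both halves (an untrained or unaugmented model scatters the synCPs
of one structure across embedding space; the augmented model collapses them
to cosine ≈ 1).

The layer update is

    h_i <- h_i + tanh(W_u [h_i, mean_j tanh(W_m [h_i, h_j, d_ij^2/100])])

with mean aggregation over contact-graph neighbors, followed by mean
pooling over nodes and a linear map to the embedding. The residual form
matters in practice: a pure replacement update collapses under synCP
augmentation at this model scale (the loss pins at its uniform value and
all embeddings coincide).

### Tunable parameters (`model_config`)

| parameter | default | meaning |
|---|---|---|
| `n_layers` | 3 | message-passing rounds (receptive field ≈ 3 contact hops) |
| `hidden_dim` | 32 | per-node feature width |
| `embed_dim` | 32 | output embedding width |
| `temperature` | 0.05 | contrastive sharpness; see below |
| `lr` | 3e-3 | Adam step size |
| `batch_families` × `members_per_family` | 6 × 4 | contrastive batch composition |
| `epochs` | 100 | passes over the family set |
| `syncp_augment` | `TRUE` | replace each sample by a random synCP |

The width/depth defaults are sized so that training runs in minutes on one
CPU in plain R; all of them scale up freely. The temperature deserves a
note: at batches of ~24 embeddings, τ = 0.05 drives unrelated families
toward genuinely low cosine (median ≈ 0.6 on a fresh benchmark), whereas
τ = 0.1 leaves the cosine scale compressed near 1 even though *rankings*
are already correct. Since the discovery filter applies absolute cutoffs
(0.6/0.9) rather than ranks, the sharper temperature is the right default
here.

Model selection during training follows validation retrieval sensitivity
(fraction of a query's true positives ranked above its first
different-fold hit, averaged over queries and over the hierarchy levels
that have true positives), evaluated all-vs-all within the validation set
every five epochs; the best checkpoint is returned.

## The aligner in detail

`align` is a deliberately simple TM-align-style heuristic, implemented in
compiled code: seeds from gapless threading at every offset and from
fragment superpositions; one superpose → score → DP sweep per seed; the
best few seeds are refined to convergence. The DP is a three-state affine
alignment with gap-open −0.6, no gap extension, and free end gaps — on
tiny inputs it provably equals exhaustive enumeration over all monotone
mappings (a test asserts this). TM-scores use
d0 = max(0.5, 1.24·(L−15)^{1/3} − 1.8) and the minimum of the
query-/target-normalized scores, with the final superposition found by
iterative subset refinement. Because the search runs in both directions and
keeps the better mapping, the reported score is symmetric in its arguments.

`align_cp` aligns the doubled query against the target, reads candidate cut
offsets from the wrapped mapping, and re-aligns the cyclically shifted
query in each candidate frame; offset 0 (the plain alignment) is always a
candidate, so `tm_cp ≥ tm` holds exactly and ΔCP is never negative. Scores
are normalized by the original chain lengths and each original residue maps
at most once. We accept that absolute scores can deviate from the reference
TM-align binary — both arms of ΔCP use the same aligner, so the difference
statistic keeps its meaning.

Numerical corner cases: mappings with fewer than three pairs cannot be
superposed and score conservatively; collinear point sets make the Kabsch
rotation ill-determined and are flagged; ties in the CP frame choice go to
the smaller offset.

## What the synthetic generator emulates — and what it does not

`make_synthetic_family` builds a rigid family template from idealized
secondary-structure elements — helix (rise 1.5 Å/residue, 100°/residue,
radius 2.3 Å), strand (rise 3.4 Å, 0.9 Å zig-zag) — joined by random-walk
loops, with a compactness bias keeping the chain within ~4.2·n^{1/3} Å of
its center so that 10 Å contact graphs have realistic density. Members are
the template plus i.i.d. Gaussian coordinate noise and a random rigid
motion. `make_cp_benchmark` additionally replaces one member per family
with a synCP (cut drawn from the central half of the chain) of another
member, plus noise, and records cross-family decoys. Everything is
deterministic per seed, and member generation is prefix-stable so extra
members can serve as held-out sets.

This emulates: labeled families of rigid, compact, secondary-structured
backbones; genuine planted circular permutants; decoys with different
global folds. It does **not** emulate: sequence-dependent geometry, loop
flexibility and domain motion, insertions/extensions around the cut (real
CP pairs are rarely exact cyclic reorderings), or the size and redundancy
structure of real domain databases. Consequently, passing tests show that
the *mechanism* (augmentation ⇒ learned invariance ⇒ dual-model contrast ⇒
alignment verification) works end-to-end; they do not calibrate recovery
rates on real structures.

A related caveat: the discovery benchmark draws from the same family
generator as the training corpus, mirroring the common design in which a
database is searched by a model trained on it. At this training scale the
invariant encoder does not transfer family separation to entirely unseen
family templates — their embeddings crowd together — so applying the
pipeline to out-of-distribution structures would require retraining on a
matching corpus.

## Study sizes used by the tests and acceptance script

Training fixture: 30 families × 8 members, chain length 80, noise 0.3 Å,
100 epochs for each of the two encoders, with 2 held-out members per
family; discovery benchmark: 10 families × 4 members with one planted CP
per family; alignment benchmark: 100 rigid planted permutants of lengths
40–70. These sizes keep the full pipeline reproducible in minutes while
leaving every quantity measurable.

## Known limitations

- **Node-level motif similarity is not established at the default training
  length.** The per-node embeddings exposed by `node_embeddings` /
  `node_similarity_map` remain dominated by sequence-position signal after
  100 epochs: the corresponding-residue band for an internally duplicated
  substructure is barely elevated over background, and the package's own
  acceptance check for this property fails at that scale (it emerges under
  substantially longer training). The maps are still useful for
  inspection, but residue-level correspondence claims should not be based
  on the default fixture model.
- The aligner handles a single circular permutation; general
  secondary-structure rewiring is only *surfaced* by embedding-score
  contrast, not explicitly aligned.
- Absolute TM scores are heuristic approximations of the reference
  implementation; all decision rules in the package use them consistently
  on both arms.
- The invariant/baseline cutoffs (0.9/0.6/0.7) are taken as fixed pipeline
  parameters; their calibration on real databases is outside the package's
  scope.
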