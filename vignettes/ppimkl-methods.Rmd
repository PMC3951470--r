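---
title: "Multiple kernels for PPI extraction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple kernels for PPI extraction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimkl)
```

## The problem and the model

Protein–protein interaction extraction asks, for one sentence with two
tagged protein mentions, whether the sentence asserts an interaction between
them. Each candidate pair is an *instance*: the tokens, the entity spans,
a constituency parse whose leaves equal the tokens, and a binary label.
Before any kernel is computed the pair is masked to `PROTEIN_1` /
`PROTEIN_2` and all other tagged proteins to `PROTEIN`, so the classifier
cannot memorize protein identities.

Classification is a soft-margin SVM over a precomputed Gram matrix built
from a linear ensemble of three kernels. Each kernel reads a different
channel of evidence:

| kernel | channel | form |
|---|---|---|
| `K_fea` | lexical surface | cosine over one-hot word/distance features |
| `K_DET` | syntactic structure | normalized convolution kernel on pruned trees |
| `K_sim` | ontology semantics | protein-pair + bipartite context similarity |

## Feature-based kernel

Six feature groups: words inside the two protein names (original surface
forms), words strictly between the pair, up to `window` (default 5) words
left of the first and right of the second mention, the first interaction
keyword found (between-region scanned before the surrounding window), the
binned count of non-protein words between the pair (`≤3`, `(3,6]`, `(6,9]`,
`>9`), and the count of other protein mentions between the pair. Empty
groups carry an explicit `"NULL"` sentinel so absence is itself a feature.

The kernel's functional form is a design choice (the source method leaves
it open): we use the cosine of binary one-hot encodings. It is symmetric,
bounded in [0, 1], has unit self-similarity, and its Gram is positive
semidefinite by construction. Binary rather than tf weighting because each
group contributes at most a handful of tokens per instance.

The keyword list defaults to *interact*, *regulate*, *modulate* plus
morphological variants; it is a plain one-word-per-line file, replaceable
via `--keywords`.

## Tree kernel and the dynamic extension

The convolution tree kernel counts shared subtree fragments: with
`C(n1, n2) = 0` when productions differ, `λ` for equal preterminal
productions, and `λ·∏(1 + C(child_j, child_j))` otherwise,
`K(T1, T2) = Σ C(n1, n2)`. A fragment with `k` productions is weighted
`λ^k`; λ defaults to 0.4, the customary decay for this kernel family (the
source method does not state its value), configurable via `--lambda`.
Values are cosine-normalized so `k_det(x, x) = 1`.

Pruning controls which part of the parse the kernel sees:

* **MCT** — subtree at the lowest common ancestor of the two protein
  leaves;
* **SPT** — the MCT with every subtree removed that lies wholly outside
  the leaf span between the proteins (span-enclosed dialect: material
  *between* the two path spines is kept, matching the printed reference
  examples, e.g. a coordinating `(CC and)` survives);
* **DET** — SPT by default; when the SPT has fewer than `threshold = 7`
  nodes it is replaced by the MCT if the two differ, else by the subtree
  at the parent of the SPT root. If the SPT root is already the sentence
  root, nothing can be added and the SPT is kept with a warning.

**Node counting.** The extension rule needs a node count, and what counts
as a node is consequential. Counting every node including token leaves
makes the canonical example `(NP (NNP PROTEIN_1) (CC and) (NNP PROTEIN_2))`
have exactly 7 nodes — not "fewer than 7" — so it would never extend,
contradicting the very example the rule was designed for. Counting labeled
syntactic nodes only (internal + preterminal) gives 4, the example extends
to the `S` tree containing `(VBP interact)`, and the published DET examples
are reproduced. We therefore default to `node_count_mode = "nonleaf"` and
expose `"all"` and `"leaves"` as options.

## Semantic kernel

`k_sim(x, y) = mix · sim_pp + (1 − mix) · sim_con`, default `mix = 0.5`.

**Concept similarity.** Over a rooted taxonomy with per-concept corpus
frequencies, `p(c)` is the cumulative frequency of `c` and its descendants
over the total (so `p(root) = 1`), `IC(c) = −log p(c)`, and depth counts
from 1 at the root. Two measures are combined:

* edge-counting: `e^{−αl} · tanh(βh)` with `l` the shortest path through
  the lowest common subsumer and `h` that subsumer's depth; α = 0.2,
  β = 0.6 are the published optima of the measure's authors;
* information content (Lin): `2·IC(lcs)/(IC(c₁)+IC(c₂))`, defined as 1
  when `c₁ = c₂` with zero IC sum and 0 when the only shared subsumer is
  the root.

The exact algebra of the source's hybrid (and of `sim_pp`, `sim_con`, and
the semantic mix) is not recoverable from the source text; each is
implemented as a documented interpretation behind a configuration knob:
hybrid = arithmetic mean (also `product`, `li_only`, `lin_only`); `sim_pp`
= positionally aligned mean `(hybrid(c₁₁,c₂₁) + hybrid(c₁₂,c₂₂))/2`
(positions are meaningful because pairs are sentence-ordered; a
cross-aligned variant was considered and not enabled by default);
`sim_con` normalized by `max(|A|, |B|)`, which keeps the value in [0, 1]
since at most `min(|A|, |B|)` words can be matched with weight ≤ 1. A
protein with no resolvable concept falls back to string identity rather
than dropping the instance, keeping the kernel total.

**Context similarity.** Contexts are the lowercased sentence tokens minus
protein placeholders and a configurable stopword list (a standard English
list ships as a fixture). Word–word weights use Lin similarity over a word
taxonomy, with out-of-vocabulary identity fallback; the maximum-weight
bipartite matching is computed exactly by the Hungarian algorithm
(O(n³) shortest augmenting path) rather than greedily.

`K_sim` is symmetric and bounded but **not** guaranteed positive
semidefinite — it is a similarity, not a Mercer kernel. The ensemble
pipeline therefore clips negative eigenvalues (`make_psd`) before training;
a matrix already PSD within tolerance is returned untouched.

## Ensemble, SVM and evaluation

The ensemble is the weighted sum of Gram matrices (equal weights by
default — weighted combination is exposed but deliberately not optimized,
matching the plain multiple-kernel setting), renormalized to unit diagonal.
The SVM solves the C-SVC dual with a deterministic SMO solver (fixed scan
order, largest-|ΔE| second choice, C default 1.0); determinism matters more
here than raw speed, because byte-identical reports under a fixed seed are
an acceptance property. Cross-validation defaults to 10 folds split by
document, so sibling pairs from one abstract never straddle a train/test
boundary (instance-level splitting is available for protocol matching).
ROC/AUC uses trapezoidal integration with half-credit ties, equal to the
Mann–Whitney statistic.

## What the synthetic generator emulates — and what it does not

The generator's world is fixed and documented, not tuned per run:

* exact positive quota (`positive_rate` of `n`), doc ids in blocks of 5;
* two sentence templates with flat scaffolds: `pre* P1 between+ P2 post*`
  and the conjunction `pre* P1 and P2 VP` (leading fillers sit in a
  sibling NP of the conjoined pair, the configuration the dynamic
  extension exists for);
* `keyword_signal`: probability a positive carries an interaction keyword
  inside the pruned-tree region (between the pair, or in the VP only the
  extension recovers) and follows the short-span regime; negatives get
  *distractor* keywords in the surrounding-but-outside-SPT region at half
  that rate, which fools the window-based lexical scan but not the tree
  kernel;
* `taxonomy_signal`: probability a positive pair's concepts are taxonomy
  siblings, and that context words come from the label-associated branch
  of the word taxonomy;
* `distance_noise`: symmetric corruption of the span-length cue;
* Zipf-weighted filler draws, and a word taxonomy (default depth 6,
  branching 3, 243 leaf words) much larger than the concept taxonomy
  (depth 4 × 3): sparse context overlap is essential — with a tiny word
  inventory the context similarity degenerates into a near-constant
  offset that only blurs the ensemble;
* surface protein names are random, so nothing about the label is
  readable from the names themselves.

With all signals at zero the classes are identically distributed and every
kernel's cross-validated AUC sits at chance — the null-world test. What a
green pipeline test establishes is that each kernel recovers the channel
planted for it and that the ensemble combines them without losing either;
it does *not* establish performance on real biomedical text, where parses
are imperfect, mention boundaries are noisy, vocabulary is open, and the
interaction vocabulary is far richer than a keyword list.

## Numerical choices and degenerate inputs

* PTB writes are bit-exact (single spaces); parse errors name the
  character offset.
* A multi-token mention collapses to one leaf under its lowest dominating
  node; a span no node covers exactly falls back to replacing the
  leftmost leaf and dropping the rest, with a warning.
* A degenerate tree with zero self-kernel gets similarity 0 (with a
  warning) instead of NaN.
* Gram symmetry is enforced at 1e−9; PSD repair tolerance defaults to
  1e−8; zero-weight matches are omitted from reported matchings (the
  total is unchanged).
* Fold assignment shuffles documents with the run seed; the SMO solver
  itself is deterministic, so the seed controls folds only.

## Known limitations

* No real-corpus adapters (AIMED XML, Stanford Parser invocation, MeSH,
  WordNet) — the formats are documented extension points.
* No stemming/lemmatization of features; no word-sense disambiguation
  (a word maps to one concept; with several, the maximum similarity would
  be taken).
* Weighted multiple-kernel optimization is out of scope; weights are a
  manual knob.
* The SMO solver targets corpora of hundreds to a few thousand instances;
  it is not engineered for corpus sizes beyond that.
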